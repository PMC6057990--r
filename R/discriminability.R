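#' Area under the ROC curve
#'
#' Discriminability of two samples as the probability of correct binary
#' classification across all thresholds, computed by the rank (Mann-Whitney)
#' formulation with ties credited one half:
#' `auc = P(X_a < X_b) + 0.5 * P(X_a = X_b)`. A value of 0.5 signifies random
#' performance; 0 and 1 signify perfect discrimination.
#'
#' @param samples_a,samples_b Non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b)) {
    stop("auc requires two non-empty samples")
  }
  stopifnot(is.numeric(samples_a), is.numeric(samples_b),
            !anyNA(samples_a), !anyNA(samples_b))
  na <- length(samples_a); nb <- length(samples_b)
  r <- rank(c(samples_a, samples_b))
  # U for sample b: number of (a, b) pairs with b > a, ties counted 1/2
  ub <- sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  ub / (na * nb)
}

# Canonical texture order and the induced pair orders.
texture_order <- c("P80", "P240", "P400", "P600", "P1200")

#' All pairwise texture comparisons in canonical order
#'
#' @param textures Character vector of texture labels; the five standard
#'   sandpapers are ordered roughest first, other labels keep their order.
#' @return data.frame with columns `texture_a`, `texture_b`, all unordered
#'   pairs with the rougher texture first.
#' @export
texture_pairs <- function(textures = texture_order) {
  textures <- unique(textures)
  known <- intersect(texture_order, textures)
  textures <- c(known, setdiff(textures, known))
  if (length(textures) < 2) stop("need at least two textures")
  cmb <- utils::combn(textures, 2)
  data.frame(texture_a = cmb[1, ], texture_b = cmb[2, ],
             stringsAsFactors = FALSE)
}

#' Pairwise texture discriminability for one coding variable
#'
#' AUC for every unordered texture pair, computed from a [build_feature_table()]
#' result. Sweep-level variables (`f`, `i`, `sr`, `sv_med`, `sa_med`) use one
#' sample per sweep; event-level variables (`sv`, `sa`) pool slip events
#' across the sweeps of each texture, matching distribution-level
#' discriminability of slip kinematics.
#'
#' @param features A `feature_table`.
#' @param variable One of `"f"`, `"i"`, `"sr"`, `"sv_med"`, `"sa_med"`
#'   (sweep-level) or `"sv"`, `"sa"` (event-level).
#' @param whisker,speed,distance Optional context filters (scalar values).
#' @return data.frame: `variable`, `texture_a`, `texture_b`, `auc`, `n_a`,
#'   `n_b`. Pairs with an empty sample get `NA` AUC.
#' @export
pairwise_auc <- function(features, variable, whisker = NULL, speed = NULL,
                         distance = NULL) {
  stopifnot(inherits(features, "feature_table"))
  event_level <- variable %in% c("sv", "sa")
  tab <- if (event_level) features$events else features$sweeps
  if (is.null(tab) || !nrow(tab)) stop("no samples available for ", variable)
  if (!variable %in% names(tab)) stop("unknown variable: ", variable)
  if (!is.null(whisker)) tab <- tab[tab$whisker == whisker, ]
  if (!is.null(speed)) tab <- tab[tab$speed == speed, ]
  if (!is.null(distance)) tab <- tab[tab$distance == distance, ]
  pairs <- texture_pairs(unique(tab$texture))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xa <- tab[[variable]][tab$texture == pairs$texture_a[i]]
    xb <- tab[[variable]][tab$texture == pairs$texture_b[i]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    data.frame(variable = variable,
               texture_a = pairs$texture_a[i], texture_b = pairs$texture_b[i],
               auc = if (length(xa) && length(xb)) auc(xa, xb) else NA_real_,
               n_a = length(xa), n_b = length(xb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Average discriminability over neighboring texture pairs
#'
#' Mean AUC-distance across the four neighboring-grain-size comparisons
#' ([P80,P240], [P240,P400], [P400,P600], [P600,P1200]). Because
#' discriminability can invert between textures (AUC below vs above 0.5),
#' each AUC is folded around chance (`0.5 + |auc - 0.5|`) before averaging so
#' opposite-signed discriminability does not cancel; the raw (unfolded)
#' average is reported alongside.
#'
#' @param results data.frame from [pairwise_auc()].
#' @return List with `folded` and `raw` mean AUC over the four neighboring
#'   pairs.
#' @export
neighbor_average <- function(results) {
  nb <- data.frame(texture_a = texture_order[1:4],
                   texture_b = texture_order[2:5])
  vals <- vapply(seq_len(nrow(nb)), function(i) {
    hit <- results$texture_a == nb$texture_a[i] &
      results$texture_b == nb$texture_b[i]
    rev <- results$texture_a == nb$texture_b[i] &
      results$texture_b == nb$texture_a[i]
    if (any(hit)) return(results$auc[which(hit)[1]])
    if (any(rev)) return(1 - results$auc[which(rev)[1]])
    NA_real_
  }, numeric(1))
  if (anyNA(vals)) stop("missing neighboring pair in results")
  list(folded = mean(0.5 + abs(vals - 0.5)), raw = mean(vals))
}
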