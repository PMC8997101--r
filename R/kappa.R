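# Weighted Cohen's kappa on ordinal ratings, category merging, and the
# reliability gate applied to recorders before their data enter benchmarking.

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two ratings of the same items on an
#' ordered categorical scale:
#' \deqn{\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}}}
#' with disagreement weights \eqn{w_{ij} = |i-j|/(k-1)} (linear, default) or
#' its square (quadratic), observed cell proportions \eqn{O} and
#' chance-expected proportions \eqn{E} from the marginals.
#'
#' @param ratings,reference equal-length vectors of ratings on `scale`.
#' @param scale the full ordered scale (e.g. `1:5`); defaults to the sorted
#'   union of observed values. Declaring the full scale matters: weights
#'   depend on category positions, including unused ones.
#' @param weights `"linear"` or `"quadratic"` disagreement weights.
#' @return An object of class `kappa_result`: list with elements `kappa`
#'   (in \eqn{[-1, 1]}, or `NA` if undefined), `observed_agreement` and
#'   `expected_agreement` (weighted), `weights`, `n`, `scale`, and
#'   `degenerate` (`TRUE` when both raters are constant and equal, in which
#'   case `kappa` is 1 by convention).
#' @seealso [merge_and_rate()], [gate_observers()]
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), scale = 1:5)$kappa  # 1
#' weighted_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2), scale = 1:2)$kappa        # ~0
weighted_kappa <- function(ratings, reference,
                           scale = sort(unique(c(ratings, reference))),
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(ratings) != length(reference))
    stop("'ratings' and 'reference' must have the same length", call. = FALSE)
  n <- length(ratings)
  if (n < 1) stop("at least one rated item is required", call. = FALSE)
  if (!all(ratings %in% scale) || !all(reference %in% scale))
    stop("ratings outside the declared scale", call. = FALSE)
  k <- length(scale)
  O <- table(factor(ratings, levels = scale),
             factor(reference, levels = scale)) / n
  E <- outer(rowSums(O), colSums(O))
  if (k > 1) {
    W <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    if (weights == "quadratic") W <- W^2
  } else {
    W <- matrix(0, 1, 1)
  }
  do <- sum(W * O)
  de <- sum(W * E)
  degenerate <- de == 0
  kappa <- if (de == 0) {
    if (do == 0) 1 else NA_real_
  } else {
    1 - do / de
  }
  structure(list(kappa = kappa,
                 observed_agreement = 1 - do,
                 expected_agreement = 1 - de,
                 weights = weights, n = n, scale = scale,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Weighted Cohen's kappa (", x$weights, " weights, n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  kappa = %.4f  [%s]\n",
              x$kappa, landis_koch(x$kappa)))
  cat(sprintf("  weighted agreement: observed %.4f, chance-expected %.4f\n",
              x$observed_agreement, x$expected_agreement))
  if (isTRUE(x$degenerate))
    cat("  note: degenerate table (no expected disagreement)\n")
  invisible(x)
}

# parse "12|3|45" into list(c(1,2), 3, c(4,5)); scale entries must be
# single characters for the string form
parse_partition <- function(partition, scale) {
  if (is.character(partition) && length(partition) == 1) {
    blocks <- strsplit(partition, "|", fixed = TRUE)[[1]]
    partition <- lapply(strsplit(blocks, ""), function(ch) {
      m <- match(ch, as.character(scale))
      if (anyNA(m)) stop("partition names categories outside the scale",
                         call. = FALSE)
      scale[m]
    })
  }
  flat <- unlist(partition)
  if (anyDuplicated(flat) || !setequal(flat, scale))
    stop("partition must cover the scale exactly once per category",
         call. = FALSE)
  # order blocks by their lowest member on the scale
  ord <- order(vapply(partition, function(b) min(match(b, scale)), 1L))
  partition[ord]
}

#' Weighted kappa after merging scale categories
#'
#' Recode both rating vectors onto the blocks of a partition of the scale
#' (blocks ordered by their lowest member) and compute [weighted_kappa()] on
#' the merged scale. The canonical use is collapsing five locomotion scores
#' to three categories, merging scores 1 + 2 (non-lame and mildly lame) and
#' 4 + 5 (clearly and severely lame): `partition = "12|3|45"`.
#'
#' @inheritParams weighted_kappa
#' @param partition a list of vectors of scale categories, or a compact
#'   string such as `"12|3|45"` for single-character categories.
#' @return A `kappa_result` on the merged scale.
#' @export
#' @examples
#' merge_and_rate(c(1, 2), c(2, 1), partition = "12|3|45", scale = 1:5)$kappa
merge_and_rate <- function(ratings, reference, partition,
                           scale = sort(unique(c(ratings, reference))),
                           weights = c("linear", "quadratic")) {
  blocks <- parse_partition(partition, scale)
  block_of <- integer(length(scale))
  for (b in seq_along(blocks)) block_of[match(blocks[[b]], scale)] <- b
  recode <- function(v) block_of[match(v, scale)]
  weighted_kappa(recode(ratings), recode(reference),
                 scale = seq_along(blocks), weights = weights)
}

#' Weighted kappa per observer from a rater-response table
#'
#' @param ratings data.frame with columns `observer_id`, `item`, `rating`,
#'   `reference` (the [clawbench_schemas()] `ratings` schema).
#' @param scale the full ordered scale; defaults to the range of observed
#'   categories.
#' @param partition optional partition passed to [merge_and_rate()].
#' @inheritParams weighted_kappa
#' @return data.frame with one row per observer: `observer_id`, `kappa`, `n`.
#' @export
kappa_by_observer <- function(ratings, scale = NULL, partition = NULL,
                              weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (is.null(scale))
    scale <- seq(min(c(ratings$rating, ratings$reference)),
                 max(c(ratings$rating, ratings$reference)))
  res <- lapply(split(ratings, ratings$observer_id), function(d) {
    kr <- if (is.null(partition)) {
      weighted_kappa(d$rating, d$reference, scale = scale, weights = weights)
    } else {
      merge_and_rate(d$rating, d$reference, partition = partition,
                     scale = scale, weights = weights)
    }
    data.frame(observer_id = d$observer_id[1], kappa = kr$kappa, n = kr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gate observers on a minimum weighted kappa
#'
#' Observers pass iff their weighted kappa meets the threshold (inclusive;
#' the conventional requirement is \eqn{\kappa \ge 0.61}, "substantial"
#' agreement). The passed set feeds the trained-observer registry used by
#' herd-level data validation.
#'
#' @param kappas named numeric vector of kappa values, or the data.frame
#'   returned by [kappa_by_observer()].
#' @param threshold minimum kappa, default 0.61.
#' @return list with character vectors `passed` and `failed`.
#' @export
#' @examples
#' gate_observers(c(a = 0.61, b = 0.55, c = 1))
gate_observers <- function(kappas, threshold = 0.61) {
  if (is.data.frame(kappas)) {
    k <- kappas$kappa
    names(k) <- kappas$observer_id
    kappas <- k
  }
  ok <- !is.na(kappas) & kappas >= threshold
  list(passed = names(kappas)[ok], failed = names(kappas)[!ok])
}

#' Landis-Koch agreement label for a kappa value
#'
#' Interpretation bands for reporting only: poor (<= 0), slight, fair,
#' moderate, substantial, almost perfect (>= 0.81).
#'
#' @param kappa numeric vector of kappa values.
#' @return Character vector of labels.
#' @export
landis_koch <- function(kappa) {
  labs <- c("poor", "slight", "fair", "moderate", "substantial",
            "almost perfect")
  out <- labs[findInterval(kappa, c(0, 0.2, 0.4, 0.6, 0.8),
                           left.open = TRUE) + 1L]
  out[is.na(kappa)] <- NA_character_
  out
}
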