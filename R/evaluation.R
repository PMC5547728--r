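# Evaluation of predicted binding sites and residues: center-distance
# success-rate curves, residue-level precision/recall/MCC, operating-point
# matching against reference methods, and the capped paired-distance
# comparison with a Wilcoxon signed-rank test.

#' Center-distance success rates
#'
#' For each protein the native ligand centers are compared with its ranked
#' predicted centers. Under the `top_n` protocol a protein with n native
#' sites contributes its top n predictions; under `top_5`, its top 5. A
#' native site is correctly predicted at cutoff D iff the minimal distance
#' from its center to any selected prediction is <= D; the success rate at D
#' is the fraction of correctly predicted sites over the whole dataset.
#' Proteins with no prediction count all their sites as failures.
#'
#' @param natives Tibble of native ligand centers: `protein`, `x`, `y`, `z`.
#' @param predictions Tibble of ranked predicted centers: `protein`, `rank`,
#'   `x`, `y`, `z`.
#' @param protocol `"top_n"` (default) or `"top_5"`.
#' @param d_grid Cutoff grid in Angstrom; default 0.5 to 10 by 0.5.
#' @return A `nucsite_dcc`: list with `per_site` (tibble `protein`, `site`,
#'   `d`) and `rates` (tibble `D`, `rate`).
#' @export
dcc_success <- function(natives, predictions, protocol = c("top_n", "top_5"),
                        d_grid = seq(0.5, 10, by = 0.5)) {
  protocol <- match.arg(protocol)
  stopifnot(nrow(natives) >= 1L)
  per_site <- natives |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(nat, key) {
      n_take <- if (protocol == "top_n") nrow(nat) else 5L
      preds <- predictions[predictions$protein == key$protein[[1L]], ]
      preds <- preds[order(preds$rank), ][seq_len(min(n_take, nrow(preds))), ]
      preds <- preds[!is.na(preds$rank), , drop = FALSE]
      d <- if (nrow(preds) == 0L) {
        rep(Inf, nrow(nat))
      } else {
        apply(cross_dist(cbind(nat$x, nat$y, nat$z),
                         cbind(preds$x, preds$y, preds$z)), 1L, min)
      }
      tibble(site = seq_len(nrow(nat)), d = d)
    }) |>
    dplyr::ungroup()
  rates <- tibble(
    D = d_grid,
    rate = vapply(d_grid, function(D) mean(per_site$d <= D), 0)
  )
  structure(list(per_site = per_site, rates = rates, protocol = protocol),
            class = "nucsite_dcc")
}

#' @export
print.nucsite_dcc <- function(x, ...) {
  cat(sprintf("<nucsite_dcc> %d native sites, protocol %s\n",
              nrow(x$per_site), x$protocol))
  at4 <- x$rates$rate[match(4, x$rates$D)]
  if (!is.na(at4)) cat(sprintf("  success rate at D = 4 A: %.1f%%\n", 100 * at4))
  invisible(x)
}

#' @describeIn dcc_success Success-rate curve as a tibble.
#' @param x A `nucsite_dcc`.
#' @method tidy nucsite_dcc
#' @export
tidy.nucsite_dcc <- function(x, ...) x$rates

#' Residue-level confusion metrics
#'
#' Precision, recall and the Matthews correlation coefficient from binary
#' truth and calls over the same residue universe. A metric whose denominator
#' is zero is reported as 0 with its flag set.
#'
#' @param truth,calls Logical vectors of equal length (same residue order).
#' @return A `nucsite_residue_eval`: list with `tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `mcc`, and `undefined` (character vector naming
#'   any zero-denominator metrics).
#' @export
residue_metrics <- function(truth, calls) {
  if (length(truth) != length(calls)) {
    abort("truth and calls must cover the same residues",
          class = "nucsite_input_error")
  }
  truth <- as.logical(truth)
  calls <- as.logical(calls)
  tp <- sum(truth & calls)
  fp <- sum(!truth & calls)
  tn <- sum(!truth & !calls)
  fn <- sum(truth & !calls)
  undefined <- character(0L)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  rec <- if (tp + fn > 0L) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else {
    undefined <- c(undefined, "mcc"); 0
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         precision = prec, recall = rec, mcc = mcc, undefined = undefined),
    class = "nucsite_residue_eval"
  )
}

#' @export
print.nucsite_residue_eval <- function(x, ...) {
  cat(sprintf(
    "<nucsite_residue_eval> TP %d FP %d TN %d FN %d | PREC %.3f REC %.3f MCC %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$precision, x$recall, x$mcc
  ))
  invisible(x)
}

#' @describeIn residue_metrics Metrics as a one-row tibble.
#' @param x A `nucsite_residue_eval`.
#' @method tidy nucsite_residue_eval
#' @export
tidy.nucsite_residue_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         precision = x$precision, recall = x$recall, mcc = x$mcc)
}

#' Match an operating point of a reference method
#'
#' Sweeps the integer score threshold over pooled (micro-averaged) residue
#' scores and returns the threshold whose aggregate precision (or recall) is
#' closest to, and at least, the reference value when attainable; otherwise
#' the closest threshold with `attained = FALSE`. Used to compare methods at
#' equal precision or equal recall.
#'
#' @param scored Tibble with columns `score` (integer per residue) and
#'   `truth` (logical), pooled over proteins.
#' @param reference Named list with exactly one of `precision` or `recall`,
#'   in (0, 1].
#' @return List with `threshold`, `metrics` (a `nucsite_residue_eval`),
#'   `attained`, and `sweep` (tibble of all thresholds).
#' @export
match_operating_point <- function(scored, reference) {
  if (nrow(scored) == 0L) {
    abort("no residue scores supplied", class = "nucsite_input_error")
  }
  what <- intersect(names(reference), c("precision", "recall"))
  stopifnot(length(what) == 1L)
  target <- reference[[what]]
  stopifnot(target > 0, target <= 1)

  thresholds <- 0:max(scored$score)
  sweep_tbl <- dplyr::bind_rows(lapply(thresholds, function(t) {
    m <- residue_metrics(scored$truth, scored$score > t)
    tibble(threshold = t, precision = m$precision, recall = m$recall,
           mcc = m$mcc)
  }))
  val <- sweep_tbl[[what]]
  ok <- val >= target
  pick <- if (any(ok)) {
    cand <- which(ok)
    diffs <- val[cand] - target
    # ties (several thresholds give the same closest value) resolve to the
    # highest threshold: the most conservative calls at that operating point
    max(cand[diffs <= min(diffs) + 1e-12])
  } else {
    cand <- seq_along(val)
    diffs <- abs(val - target)
    max(cand[diffs <= min(diffs) + 1e-12])
  }
  list(
    threshold = sweep_tbl$threshold[pick],
    metrics = residue_metrics(scored$truth,
                              scored$score > sweep_tbl$threshold[pick]),
    attained = any(ok),
    sweep = sweep_tbl
  )
}

#' Capped paired-distance comparison of two methods
#'
#' Per-site minimal center distances from two methods are paired; distances
#' beyond `cap` (default 10 A) are rounded down to the cap, treating all
#' far-off predictions as equally wrong, and the Wilcoxon signed-rank test is
#' applied to the capped pairs. If every pair ties after capping the test is
#' degenerate and no p-value is reported.
#'
#' @param d_a,d_b Equal-length numeric vectors of per-site distances.
#' @param cap Capping distance in Angstrom; default 10.
#' @return List with `capped_a`, `capped_b`, `p_value`, `direction`
#'   (sign of median(capped_a - capped_b): -1 means method A closer),
#'   and `degenerate`.
#' @export
capped_distance_pairs <- function(d_a, d_b, cap = 10) {
  stopifnot(length(d_a) == length(d_b), cap > 0)
  ca <- pmin(d_a, cap)
  cb <- pmin(d_b, cap)
  diffs <- ca - cb
  if (all(diffs == 0)) {
    return(list(capped_a = ca, capped_b = cb, p_value = NA_real_,
                direction = 0, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(ca, cb, paired = TRUE, exact = FALSE))
  list(capped_a = ca, capped_b = cb, p_value = wt$p.value,
       direction = sign(median(diffs)), degenerate = FALSE)
}
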