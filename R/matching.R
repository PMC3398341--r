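# Reference/Test patient matching by thorax measurements.
#
# Three measurements characterize the thorax on an anterior radiograph: the
# inner-rib horizontal gaps W1 (upper row, T2/T3 analog) and W2 (lower row,
# T9/T10 analog) and the vertical row distance L. Patients are matched
# within their own group by the lowest root-sum-of-squared-differences
# (least-squares difference, LSD) over the (W1, W2, L) triple.

#' Construct a thorax measurement record
#'
#' @param subject_id Subject identifier.
#' @param group_label Categorical matching group (e.g. "M"/"F").
#' @param W1,W2,L Measurements in cm (all > 0).
#' @return An object of class `thorax_measurements`.
#' @export
thorax_measurements <- function(subject_id, group_label, W1, W2, L) {
  if (any(c(W1, W2, L) <= 0) || any(!is.finite(c(W1, W2, L)))) {
    stop("W1, W2, L must be positive finite numbers (cm)", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 group_label = as.character(group_label),
                 W1 = W1, W2 = W2, L = L),
            class = "thorax_measurements")
}

#' @export
print.thorax_measurements <- function(x, ...) {
  cat(sprintf("<thorax_measurements> %s [%s] W1=%.1f W2=%.1f L=%.1f cm\n",
              x$subject_id, x$group_label, x$W1, x$W2, x$L))
  invisible(x)
}

#' Measure W1, W2, L on a radiograph
#'
#' Extracts the horizontal intensity profile at each row and finds the inner
#' rib borders as the innermost *outward-rising* gradient peaks above a
#' relative threshold on each side of the midline. Rising-vs-falling
#' disambiguation matters: walking outward from the midline, the inner rib
#' border is a soft-tissue-to-bone step (intensity rises), whereas the spine
#' border and the heart silhouette are falling edges, so neither can be
#' mistaken for a rib. `L` is simply `lower_row_y - upper_row_y`.
#'
#' The two row heights are user inputs: identifying the vertebral levels is
#' a manual anatomical task (phantom CTs carry them as attributes).
#'
#' @param drr A [drr_image()].
#' @param upper_row_y,lower_row_y Row heights (cm, world frame); the upper
#'   row must be superior (smaller y).
#' @param band_halfwidth Half-height (cm) of the averaging band around each
#'   row (default 0.3).
#' @param grad_frac Relative gradient threshold as a fraction of the
#'   strongest qualifying edge on the side (default 0.5).
#' @param subject_id,group_label Metadata for the record (defaults taken
#'   from the image).
#' @return A [thorax_measurements()].
#' @export
measure_thorax <- function(drr, upper_row_y = attr(drr, "upper_row_y"),
                           lower_row_y = attr(drr, "lower_row_y"),
                           band_halfwidth = 0.3, grad_frac = 0.5,
                           subject_id = drr$subject_id,
                           group_label = drr$group_label) {
  stopifnot(inherits(drr, "drr_image"))
  if (is.null(upper_row_y) || is.null(lower_row_y)) {
    stop("row heights must be supplied (or present as image attributes)",
         call. = FALSE)
  }
  if (!(upper_row_y < lower_row_y)) {
    stop("rows out of order: `upper_row_y` must be superior (smaller y)",
         call. = FALSE)
  }
  ctr <- drr_px_centers(drr)
  if (upper_row_y < min(ctr$y) || lower_row_y > max(ctr$y)) {
    stop("row lies outside the image", call. = FALSE)
  }
  xmid <- mean(range(ctr$x))
  width_at <- function(row_y, label) {
    rows <- which(abs(ctr$y - row_y) <= band_halfwidth)
    if (!length(rows)) rows <- which.min(abs(ctr$y - row_y))
    prof <- colMeans(drr$pixels[rows, , drop = FALSE])
    g <- diff(prof) / drr$pixel_spacing[1]
    xg <- (ctr$x[-1] + ctr$x[-length(ctr$x)]) / 2
    right <- which(xg > xmid & g > 0)
    left <- which(xg < xmid & g < 0)
    if (!length(right) || !length(left)) {
      stop(sprintf("no flanking rib edges found on the %s row (y = %g cm)",
                   label, row_y), call. = FALSE)
    }
    thr_r <- grad_frac * max(g[right])
    thr_l <- grad_frac * max(-g[left])
    right <- right[g[right] >= thr_r]
    left <- left[-g[left] >= thr_l]
    # innermost qualifying run on each side; peak gradient within the run
    run_r <- right[seq_len(which.max(c(diff(right) != 1L, TRUE)))]
    xr <- xg[run_r[which.max(g[run_r])]]
    left <- rev(left)
    run_l <- left[seq_len(which.max(c(diff(left) != -1L, TRUE)))]
    xl <- xg[run_l[which.max(-g[run_l])]]
    if (xr <= xl) {
      stop(sprintf("degenerate rib-edge geometry on the %s row", label),
           call. = FALSE)
    }
    xr - xl
  }
  thorax_measurements(
    subject_id = subject_id %||% "unknown",
    group_label = group_label %||% "unknown",
    W1 = width_at(upper_row_y, "upper"),
    W2 = width_at(lower_row_y, "lower"),
    L = lower_row_y - upper_row_y)
}

#' Least-squares difference between two thorax measurement triples
#'
#' `sqrt((W1_t - W1_r)^2 + (W2_t - W2_r)^2 + (L_t - L_r)^2)`; symmetric and
#' non-negative, a Euclidean distance on the measurement triple.
#'
#' @param ref,test [thorax_measurements()] records.
#' @return LSD in cm.
#' @export
lsd <- function(ref, test) {
  stopifnot(inherits(ref, "thorax_measurements"),
            inherits(test, "thorax_measurements"))
  sqrt((test$W1 - ref$W1)^2 + (test$W2 - ref$W2)^2 + (test$L - ref$L)^2)
}

#' Select the best Reference for each Test subject
#'
#' Per Test subject, picks the same-group Reference with the lowest LSD
#' (ties broken by lexicographic reference id, for determinism). A Reference
#' may serve several Tests. The full candidate score table is retained for
#' audit.
#'
#' @param refs,tests Lists of [thorax_measurements()].
#' @return An object of class `match_result`: `pairs` (data frame
#'   `test_id`, `ref_id`, `lsd`) and `scores` (all same-group candidates).
#' @export
select_matches <- function(refs, tests) {
  stopifnot(length(refs) >= 1L, length(tests) >= 1L)
  ref_groups <- vapply(refs, `[[`, character(1), "group_label")
  ref_ids <- vapply(refs, `[[`, character(1), "subject_id")
  scores <- list()
  pairs <- list()
  for (tm in tests) {
    cand <- which(ref_groups == tm$group_label)
    if (!length(cand)) {
      stop(sprintf("no reference candidates in group '%s' for test '%s'",
                   tm$group_label, tm$subject_id), call. = FALSE)
    }
    sc <- vapply(cand, function(i) lsd(refs[[i]], tm), numeric(1))
    scores[[length(scores) + 1L]] <- data.frame(
      test_id = tm$subject_id, ref_id = ref_ids[cand],
      group = tm$group_label, lsd = sc, stringsAsFactors = FALSE)
    o <- order(sc, ref_ids[cand])
    best <- cand[o[1L]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      test_id = tm$subject_id, ref_id = ref_ids[best], lsd = min(sc),
      stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, pairs),
                 scores = do.call(rbind, scores)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s):\n", nrow(x$pairs)))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
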