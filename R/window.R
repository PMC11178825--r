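#' Aggregate per-position profiles across target sites
#'
#' For every protospacer position and conversion type, averages efficiency
#' across only those sites whose reference base at that position admits the
#' conversion (a site with no C at position 5 contributes nothing to the
#' position-5 C>T mean). SEM uses the sample standard deviation (n-1
#' denominator) and is `NA` for fewer than two eligible sites.
#'
#' @param profiles list of per-position profiles (the `$profile` element of
#'   [quantify_site()] results, or `site_quant` objects directly).
#' @return data.frame of class `window_summary`: `position`, `conversion`,
#'   `mean`, `sem`, `n` (eligible sites). Site order does not affect the
#'   result.
#' @export
aggregate_positions <- function(profiles) {
  if (length(profiles) == 0) stop("at least one profile required")
  profiles <- lapply(profiles, function(p) {
    if (inherits(p, "site_quant")) p$profile else p
  })
  long <- do.call(rbind, profiles)
  out <- NULL
  for (conv in c("C>T", "A>G", "C>G")) {
    for (p in 1:20) {
      e <- long$efficiency[long$position == p & long$conversion == conv]
      e <- e[!is.na(e)]
      n <- length(e)
      out <- rbind(out, data.frame(
        position = p, conversion = conv,
        mean = if (n > 0) mean(e) else NA_real_,
        sem = if (n >= 2) sd(e) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE))
    }
  }
  structure(out, class = c("window_summary", "data.frame"))
}

#' Infer the editing window from an aggregated profile
#'
#' The window is the maximal contiguous run of protospacer positions whose
#' mean efficiency reaches `threshold_fraction` times the maximum position
#' mean (half-max by default). When several runs tie in length, the run
#' containing the argmax wins. Positions with no eligible site break runs.
#'
#' @param summary a [aggregate_positions()] result.
#' @param conversion `"C>T"`, `"A>G"` or `"C>G"`.
#' @param threshold_fraction fraction of the peak mean a position must reach
#'   (default 0.5).
#' @return integer vector `c(start, end)` of the inclusive window interval.
#' @export
infer_window <- function(summary, conversion = "C>T",
                         threshold_fraction = 0.5) {
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1)
    stop("threshold_fraction must lie in (0,1]")
  s <- summary[summary$conversion == conversion, , drop = FALSE]
  s <- s[order(s$position), ]
  m <- rep(NA_real_, 20)
  m[s$position] <- s$mean
  if (all(is.na(m)) || max(m, na.rm = TRUE) <= 0)
    stop("all-zero profile for ", conversion, ": no window can be inferred")
  peak <- max(m, na.rm = TRUE)
  argmax <- which.max(ifelse(is.na(m), -Inf, m))
  above <- !is.na(m) & m >= threshold_fraction * peak
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  lens <- runs$lengths[cand]
  best <- cand[lens == max(lens)]
  if (length(best) > 1) {
    holds <- vapply(best, function(b)
      starts[b] <= argmax && argmax <= ends[b], logical(1))
    best <- if (any(holds)) best[which(holds)[1]] else best[1]
  }
  c(start = starts[best], end = ends[best])
}
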