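#' Quantify base-editing outcomes at one target site
#'
#' Turns per-read outcomes (from [analyze_reads()], or a list of
#' [classify_read()] results) into the three site deliverables: a
#' per-position efficiency profile, a ranked allele table, and a site
#' summary. Efficiency denominators are informative reads (retained,
#' non-indel); indel frequency is reported against all retained reads, so
#' substitution efficiency and indel frequency stay separate quantities.
#' Reads carrying both C>T and A>G count once in the `SIMULTANEOUS` class
#' tally but contribute to both per-position numerators, keeping profiles
#' marginal and class tallies a partition.
#'
#' @param outcomes data.frame from [analyze_reads()] (columns `read_id`,
#'   `status`, `class`, `edits`, `allele`) or a list of `ReadOutcome`s.
#' @param site the [target_site()].
#' @return list of class `site_quant`:
#' \describe{
#'   \item{profile}{data.frame (`position`, `ref_base`, `conversion`,
#'     `edited`, `informative`, `efficiency`), one row per position x
#'     admissible conversion (C>T and C>G at C positions, A>G at A
#'     positions).}
#'   \item{alleles}{data.frame (`allele`, `count`, `ratio`, `is_ref`) over
#'     informative reads, ratios summing to 1.}
#'   \item{summary}{list: read accounting (`n_input`, `n_discarded`,
#'     `n_retained`, `n_informative`, `n_indel`), `class_counts`, site-level
#'     efficiencies `c_to_t`, `a_to_g`, `c_to_g` (fraction of informative
#'     reads carrying at least one such conversion), their
#'     `max_per_position` variants, and `indel_frequency`.}
#' }
#' @export
quantify_site <- function(outcomes, site) {
  stopifnot(inherits(site, "TargetSite"))
  if (is.list(outcomes) && !is.data.frame(outcomes)) {
    outcomes <- outcomes_to_df(outcomes)
  }
  n_input <- nrow(outcomes)
  retained <- outcomes[outcomes$status == "retained", , drop = FALSE]
  if (nrow(retained) == 0) stop("no retained reads at site ", site$site_id)
  informative <- retained[retained$class != "INDEL", , drop = FALSE]
  n_inf <- nrow(informative)
  ref <- chars(site$protospacer)

  # Per-position conversion counts from the edit tokens.
  tok <- unlist(strsplit(informative$edits[informative$edits != ""], ";",
                         fixed = TRUE), use.names = FALSE)
  grid <- NULL
  for (p in 1:20) {
    convs <- switch(ref[p], C = c("C>T", "C>G"), A = "A>G", character(0))
    if (length(convs) > 0)
      grid <- rbind(grid, data.frame(position = p, ref_base = ref[p],
                                     conversion = convs,
                                     stringsAsFactors = FALSE))
  }
  if (is.null(grid)) {
    profile <- data.frame(position = integer(), ref_base = character(),
                          conversion = character(), edited = integer(),
                          informative = integer(), efficiency = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    key <- paste0(grid$position, ":", grid$conversion)
    counts <- table(tok)
    grid$edited <- as.integer(ifelse(key %in% names(counts),
                                     counts[key], 0L))
    grid$informative <- n_inf
    grid$efficiency <- if (n_inf > 0) grid$edited / n_inf else NA_real_
    profile <- grid
  }

  # Allele table over informative reads.
  if (n_inf > 0) {
    tab <- table(informative$allele)
    alleles <- data.frame(allele = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE)
    alleles$ratio <- alleles$count / n_inf
    alleles$is_ref <- alleles$allele == site$protospacer
    alleles <- alleles[order(-alleles$count, alleles$allele), ]
    rownames(alleles) <- NULL
  } else {
    alleles <- data.frame(allele = character(), count = integer(),
                          ratio = numeric(), is_ref = logical(),
                          stringsAsFactors = FALSE)
  }

  has_conv <- function(conv) {
    if (n_inf == 0) return(0)
    sum(grepl(paste0(":", conv), informative$edits, fixed = TRUE)) / n_inf
  }
  max_eff <- function(conv) {
    e <- profile$efficiency[profile$conversion == conv]
    if (length(e) == 0) 0 else max(e)
  }
  n_indel <- sum(retained$class == "INDEL")
  class_counts <- setNames(integer(length(OUTCOME_CLASSES)), OUTCOME_CLASSES)
  cc <- table(retained$class)
  class_counts[names(cc)] <- as.integer(cc)

  summary <- list(
    site_id = site$site_id,
    n_input = n_input,
    n_discarded = n_input - nrow(retained),
    n_retained = nrow(retained),
    n_informative = n_inf,
    n_indel = n_indel,
    class_counts = as.list(class_counts),
    c_to_t = has_conv("C>T"),
    a_to_g = has_conv("A>G"),
    c_to_g = has_conv("C>G"),
    c_to_t_max_per_position = max_eff("C>T"),
    a_to_g_max_per_position = max_eff("A>G"),
    c_to_g_max_per_position = max_eff("C>G"),
    indel_frequency = n_indel / nrow(retained)
  )
  structure(list(profile = profile, alleles = alleles, summary = summary),
            class = "site_quant")
}

outcomes_to_df <- function(lst) {
  do.call(rbind, lapply(lst, function(o) {
    stopifnot(inherits(o, "ReadOutcome"))
    data.frame(
      read_id = o$read_id, status = "retained", class = o$class,
      edits = if (nrow(o$edited_positions))
        paste(o$edited_positions$position, ":", o$edited_positions$conversion,
              sep = "", collapse = ";") else "",
      allele = o$allele, stringsAsFactors = FALSE)
  }))
}

#' @exportS3Method base::print
print.site_quant <- function(x, ...) {
  s <- x$summary
  cat("site_quant ", s$site_id, ": ", s$n_input, " reads (",
      s$n_informative, " informative, ", s$n_indel, " indel, ",
      s$n_discarded, " discarded)\n", sep = "")
  cat(sprintf("  C>T %.3f  A>G %.3f  C>G %.3f  indel %.4f\n",
              s$c_to_t, s$a_to_g, s$c_to_g, s$indel_frequency))
  invisible(x)
}

#' Top-ranked alleles at a site
#'
#' Ranks alleles by read count (descending, ties broken lexicographically by
#' allele sequence) and returns the first `k`, always including the reference
#' allele (appended when it falls outside the top `k`).
#'
#' @param alleles allele table from [quantify_site()] (`$alleles`), or a
#'   `site_quant`.
#' @param k number of alleles to report.
#' @return data.frame `allele`, `count`, `ratio`, `is_ref`.
#' @export
top_alleles <- function(alleles, k = 10) {
  if (inherits(alleles, "site_quant")) alleles <- alleles$alleles
  if (!is_count(k, 1)) stop("k must be a positive integer")
  alleles <- alleles[order(-alleles$count, alleles$allele), , drop = FALSE]
  out <- head(alleles, k)
  ref_row <- alleles[alleles$is_ref, , drop = FALSE]
  if (nrow(ref_row) > 0 && !any(out$is_ref)) out <- rbind(out, ref_row)
  rownames(out) <- NULL
  out
}
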