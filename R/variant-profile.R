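#' Intersect variant callsets
#'
#' Keeps variants present in every callset, keyed by
#' `(chrom, pos, ref, alt)`; allele frequency and depth are taken from the
#' first callset. Mirrors the consensus step of multi-caller pipelines.
#' Commutative and idempotent over callsets.
#'
#' @param callsets list (>= 2) of variant data.frames with columns `chrom`,
#'   `pos`, `ref`, `alt` (plus any others, carried from the first callset).
#' @return data.frame, the rows of the first callset present in all others.
#' @export
intersect_callsets <- function(callsets) {
  if (!is.list(callsets) || length(callsets) < 2)
    stop("at least two callsets required")
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  common <- Reduce(intersect, lapply(callsets, key))
  first <- callsets[[1]]
  out <- first[key(first) %in% common, , drop = FALSE]
  out <- out[!duplicated(key(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an SNV into one of six pyrimidine-anchored classes
#'
#' Purine-anchored pairs are collapsed onto their complements, so G>A reports
#' as C>T and A>C as T>G; complementing both alleles never changes the class.
#'
#' @param ref,alt single bases (vectorized).
#' @return character vector over `{"C>T","C>A","C>G","T>A","T>C","T>G"}`.
#' @export
#' @examples
#' classify_snv_type(c("C", "G", "A"), c("T", "A", "C"))
classify_snv_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (any(!ref %in% DNA_BASES | !alt %in% DNA_BASES))
    stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  paste0(r, ">", a)
}

#' Call zygosity from allele frequency
#'
#' Diploid regenerated-plant rule: allele frequency above 0.7 is homozygous
#' (biallelic), above 0.3 heterozygous (monoallelic), otherwise subclonal.
#' Both thresholds are strict, so boundary values fall to the lower class.
#'
#' @param af allele frequencies in (0, 1] (vectorized).
#' @param het_threshold,hom_threshold strict lower cutoffs (defaults 0.3 and
#'   0.7).
#' @return character vector over
#'   `{"subclonal","heterozygous","homozygous"}`.
#' @export
#' @examples
#' call_zygosity(c(0.1, 0.5, 0.7, 0.85))
call_zygosity <- function(af, het_threshold = 0.3, hom_threshold = 0.7) {
  if (any(!is.finite(af) | af <= 0 | af > 1))
    stop("allele frequencies must lie in (0,1]")
  if (het_threshold >= hom_threshold)
    stop("het_threshold must be below hom_threshold")
  ifelse(af > hom_threshold, "homozygous",
         ifelse(af > het_threshold, "heterozygous", "subclonal"))
}

#' Per-plant variant tallies
#'
#' Counts indels, SNVs, SNVs per six-type class and SNVs per chromosome for
#' each plant. Class counts always sum to the SNV total.
#'
#' @param plants named list of per-plant variant tables (see
#'   [simulate_plant_cohort()] / [read_plant_vcf()]).
#' @return list with `per_plant` (data.frame: `sample_id`, `n_indels`,
#'   `n_snvs`, one column per SNV class), and `per_chromosome` (data.frame:
#'   `sample_id`, `chrom`, `n_snvs`).
#' @export
per_plant_counts <- function(plants) {
  if (is.data.frame(plants)) plants <- list(plants)
  per_plant <- NULL; per_chrom <- NULL
  for (i in seq_along(plants)) {
    tab <- plants[[i]]
    sid <- if (!is.null(names(plants)) && nzchar(names(plants)[i]))
      names(plants)[i]
    else if (nrow(tab) > 0 && "sample_id" %in% names(tab)) tab$sample_id[1]
    else paste0("plant", i)
    is_snv <- if (nrow(tab) > 0) nchar(tab$ref) == 1 & nchar(tab$alt) == 1
              else logical(0)
    snvs <- tab[is_snv, , drop = FALSE]
    cls_counts <- setNames(integer(6), SNV_CLASSES)
    if (nrow(snvs) > 0) {
      cc <- table(classify_snv_type(snvs$ref, snvs$alt))
      cls_counts[names(cc)] <- as.integer(cc)
    }
    row <- data.frame(sample_id = sid, n_indels = sum(!is_snv),
                      n_snvs = nrow(snvs), stringsAsFactors = FALSE)
    for (cl in SNV_CLASSES) row[[cl]] <- cls_counts[[cl]]
    per_plant <- rbind(per_plant, row)
    if (nrow(snvs) > 0) {
      ct <- table(snvs$chrom)
      per_chrom <- rbind(per_chrom, data.frame(
        sample_id = sid, chrom = names(ct), n_snvs = as.integer(ct),
        stringsAsFactors = FALSE))
    }
  }
  list(per_plant = per_plant, per_chromosome = per_chrom)
}

#' Fraction of likely germline-transmittable SNVs
#'
#' Heterozygous or homozygous calls (allele frequency above the heterozygous
#' threshold) divided by all SNVs in the plant.
#'
#' @param plant per-plant variant table with an `af` column.
#' @param het_threshold,hom_threshold passed to [call_zygosity()].
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' germline_fraction(data.frame(ref = "C", alt = "T",
#'                              af = c(0.1, 0.5, 0.8, 0.9)))
germline_fraction <- function(plant, het_threshold = 0.3,
                              hom_threshold = 0.7) {
  snvs <- plant[nchar(plant$ref) == 1 & nchar(plant$alt) == 1, , drop = FALSE]
  if (nrow(snvs) == 0) stop("germline_fraction() is undefined with no SNVs")
  z <- call_zygosity(snvs$af, het_threshold, hom_threshold)
  mean(z %in% c("heterozygous", "homozygous"))
}

#' Plant-by-site on-target genotype matrix
#'
#' For each plant and genomic target site, a cell is `"biallelic"` if any
#' consistent conversion SNV inside the protospacer has allele frequency
#' above `hom_threshold`, `"edited"` above `het_threshold`, else
#' `"unedited"`. Conversions are resolved to the protospacer strand as in
#' [attribute_snvs()].
#'
#' @param plants named list of per-plant variant tables.
#' @param target_sites data.frame of genomic sites: `site_id`, `chrom`,
#'   `start` (0-based protospacer start), `strand` (a
#'   [plant_candidate_sites()] registry with a `site_id` column works).
#' @param conversion conversion type the matrix reports, on the protospacer
#'   strand: `"C>T"`, `"A>G"` or `"C>G"`.
#' @param het_threshold,hom_threshold strict AF cutoffs (defaults 0.3, 0.7).
#' @return character matrix, rows = plants, columns = site ids, values in
#'   `{"unedited","edited","biallelic"}`.
#' @export
on_target_genotype_matrix <- function(plants, target_sites,
                                      conversion = "C>T",
                                      het_threshold = 0.3,
                                      hom_threshold = 0.7) {
  stopifnot(conversion %in% c("C>T", "A>G", "C>G"))
  sites <- as.data.frame(target_sites, stringsAsFactors = FALSE)
  if (!"end" %in% names(sites)) sites$end <- sites$start + 20L
  cand <- data.frame(chrom = sites$chrom, start = sites$start,
                     end = sites$end, strand = sites$strand,
                     mismatch_count = 0L, source_gRNA = sites$site_id,
                     stringsAsFactors = FALSE)
  m <- matrix("unedited", nrow = length(plants), ncol = nrow(sites),
              dimnames = list(names(plants), sites$site_id))
  for (i in seq_along(plants)) {
    tab <- plants[[i]]
    snvs <- tab[nchar(tab$ref) == 1 & nchar(tab$alt) == 1, , drop = FALSE]
    if (nrow(snvs) == 0) next
    att <- attribute_snvs(snvs, cand)
    att <- att[att$conversion == conversion, , drop = FALSE]
    if (nrow(att) == 0) next
    for (sid in unique(att$source_gRNA)) {
      af_max <- max(att$af[att$source_gRNA == sid], na.rm = TRUE)
      m[i, sid] <- if (af_max > hom_threshold) "biallelic"
                   else if (af_max > het_threshold) "edited"
                   else "unedited"
    }
  }
  m
}

#' Flanking-context motif matrix for one conversion type
#'
#' Extracts the 3-mer centered on each mutated base, reported on the strand
#' where the mutated base is C (for C>T / G>A records) or A (for A>G / T>C),
#' and tabulates per-position base frequencies with information content
#' R = 2 - H bits, H the Shannon entropy (no small-sample correction).
#' Records at chromosome edges lacking a full flank are skipped and counted.
#'
#' @param snvs variant table restricted to one conversion family; rows whose
#'   (ref, alt) do not belong to `conversion` (or its complement) are
#'   dropped.
#' @param genome named character vector of chromosome sequences.
#' @param conversion `"C>T"` or `"A>G"` (pyrimidine/purine anchored forms of
#'   the two editor conversions).
#' @return list of class `motif_matrix`: `freq` (3 x 4 matrix, rows =
#'   positions 1..3 with the mutated base at position 2, columns A/C/G/T),
#'   `information` (bits per position), `n_used`, `n_skipped`.
#' @export
motif_context <- function(snvs, genome, conversion = c("C>T", "A>G")) {
  conversion <- match.arg(conversion)
  anchor <- substr(conversion, 1, 1)                  # C or A
  comp_pair <- paste0(complement_base(anchor), ">",
                      complement_base(substr(conversion, 3, 3)))
  pair <- paste0(snvs$ref, ">", snvs$alt)
  keep <- snvs[pair == conversion | pair == comp_pair, , drop = FALSE]
  if (nrow(keep) == 0) stop("no SNVs of conversion ", conversion)
  counts <- matrix(0L, nrow = 3, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(keep))) {
    ch <- keep$chrom[i]; pos <- keep$pos[i]
    if (!ch %in% names(genome)) { n_skipped <- n_skipped + 1L; next }
    L <- nchar(genome[[ch]])
    if (pos - 1 < 1 || pos + 1 > L) { n_skipped <- n_skipped + 1L; next }
    mer <- substr(genome[[ch]], pos - 1, pos + 1)
    if (keep$ref[i] != anchor) mer <- revcomp(mer)  # report on anchor strand
    cc <- chars(mer)
    if (any(!cc %in% DNA_BASES)) { n_skipped <- n_skipped + 1L; next }
    for (k in 1:3) counts[k, cc[k]] <- counts[k, cc[k]] + 1L
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable SNVs (all lacked full flanks)")
  freq <- counts / n_used
  info <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(freq = freq, information = info, n_used = n_used,
                 n_skipped = n_skipped),
            class = "motif_matrix")
}

#' @exportS3Method base::print
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix over", x$n_used, "SNVs (", x$n_skipped, "skipped )\n")
  print(round(x$freq, 3))
  cat("information (bits):", paste(round(x$information, 3), collapse = " "),
      "\n")
  invisible(x)
}
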