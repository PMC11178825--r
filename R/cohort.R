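SNV_CLASSES <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")

# AF draw ranges per zygosity class; kept strictly inside the classification
# bands (0, 0.3], (0.3, 0.7], (0.7, 1] so planted truth labels are recoverable
# exactly.
ZYGOSITY_AF_RANGES <- list(
  subclonal    = c(0.05, 0.29),
  heterozygous = c(0.31, 0.69),
  homozygous   = c(0.71, 1.00)
)

#' Simulate a cohort of plant variant tables
#'
#' Builds per-plant DNA or RNA variant tables containing (i) planted on/off-
#' target base edits at specified allele frequencies, with ref/alt resolved to
#' the forward genome strand, and (ii) Poisson-distributed background
#' (somaclonal-style) SNVs drawn from a six-class spectrum with allele
#' frequencies from a subclonal/heterozygous/homozygous mixture, plus
#' background small indels at a separate rate.
#'
#' @param genome named character vector of chromosome sequences.
#' @param edit_spec `NULL`, or a data.frame describing planted edits, one row
#'   per (site, edited position): columns `site_id`, `chrom`, `start`
#'   (0-based protospacer start), `strand`, `position` (protospacer position
#'   1..20), `conversion` (protospacer-strand, one of `"C>T"`, `"A>G"`,
#'   `"C>G"`), `af`. Each edit is planted in every plant.
#' @param background list with `mean_snvs` (Poisson mean per plant),
#'   `spectrum` (named numeric over the six pyrimidine-anchored classes,
#'   summing to 1), `af_mixture` (named weights over
#'   `subclonal`/`heterozygous`/`homozygous`), `mean_indels` (Poisson mean,
#'   default 0), and optionally `avoid` (data.frame `chrom`,`start`,`end`,
#'   0-based half-open intervals background variants must not fall into).
#' @param n_plants cohort size.
#' @param seed integer seed.
#' @param molecule `"DNA"` or `"RNA"` label carried on every record.
#' @return list with `plants` (named list of per-plant data.frames:
#'   `chrom`, `pos` 1-based, `ref`, `alt`, `af`, `depth`, `sample_id`,
#'   `molecule`, `type` (`"SNV"`/`"INDEL"`)) and `truth` (data.frame of all
#'   planted and background records with `origin` and, for background SNVs,
#'   the generating `class` and `zygosity`).
#' @export
simulate_plant_cohort <- function(genome, edit_spec = NULL,
                                  background = list(mean_snvs = 0),
                                  n_plants = 1, seed = 1,
                                  molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!is_count(n_plants, 1)) stop("n_plants must be a positive integer")
  bg <- background
  mean_snvs <- if (is.null(bg$mean_snvs)) 0 else bg$mean_snvs
  mean_indels <- if (is.null(bg$mean_indels)) 0 else bg$mean_indels
  spectrum <- bg$spectrum
  if (is.null(spectrum))
    spectrum <- setNames(rep(1 / 6, 6), SNV_CLASSES)
  if (!setequal(names(spectrum), SNV_CLASSES))
    stop("spectrum must be named by the six classes ",
         paste(SNV_CLASSES, collapse = ", "))
  spectrum <- spectrum[SNV_CLASSES]
  if (abs(sum(spectrum) - 1) > 1e-9) stop("spectrum must sum to 1")
  af_mix <- bg$af_mixture
  if (is.null(af_mix))
    af_mix <- c(subclonal = 0.3, heterozygous = 0.4, homozygous = 0.3)
  if (!setequal(names(af_mix), names(ZYGOSITY_AF_RANGES)))
    stop("af_mixture must be named subclonal/heterozygous/homozygous")
  af_mix <- af_mix / sum(af_mix)

  # Pre-resolve planted edits to genome coordinates and check the reference.
  planted <- NULL
  if (!is.null(edit_spec) && nrow(edit_spec) > 0) {
    if (any(!edit_spec$conversion %in% c("C>T", "A>G", "C>G")))
      stop("edit_spec conversions must be C>T, A>G or C>G (protospacer strand)")
    if (any(edit_spec$af <= 0 | edit_spec$af > 1))
      stop("edit_spec AFs must lie in (0,1]")
    from <- substr(edit_spec$conversion, 1, 1)
    to <- substr(edit_spec$conversion, 3, 3)
    plus <- edit_spec$strand == "+"
    pos0 <- ifelse(plus, edit_spec$start + edit_spec$position - 1L,
                   edit_spec$start + 20L - edit_spec$position)
    ref <- ifelse(plus, from, complement_base(from))
    alt <- ifelse(plus, to, complement_base(to))
    genome_base <- vapply(seq_len(nrow(edit_spec)), function(i)
      substr(genome[[edit_spec$chrom[i]]], pos0[i] + 1, pos0[i] + 1),
      character(1))
    bad <- which(genome_base != ref)
    if (length(bad) > 0)
      stop("planted edit ", bad[1], " inconsistent with genome reference (",
           genome_base[bad[1]], " at ", edit_spec$chrom[bad[1]], ":",
           pos0[bad[1]] + 1, ", expected ", ref[bad[1]], ")")
    planted <- data.frame(
      chrom = edit_spec$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
      af = edit_spec$af, site_id = edit_spec$site_id,
      position = edit_spec$position, conversion = edit_spec$conversion,
      stringsAsFactors = FALSE)
  }

  # Per-chromosome indices of pyrimidine-class bases, for spectrum-faithful
  # background placement.
  base_index <- lapply(genome, function(g) {
    cc <- chars(toupper(g))
    list(CG = which(cc %in% c("C", "G")), TA = which(cc %in% c("T", "A")))
  })
  avoid <- bg$avoid
  in_avoid <- function(ch, pos1) {
    if (is.null(avoid)) return(FALSE)
    any(avoid$chrom == ch & pos1 > avoid$start & pos1 <= avoid$end)
  }
  chrom_w <- nchar(genome) / sum(nchar(genome))

  with_rng(seed, {
    plants <- vector("list", n_plants)
    truth <- list()
    for (pl in seq_len(n_plants)) {
      sid <- sprintf("plant%03d", pl)
      rows <- list()
      if (!is.null(planted)) {
        pr <- planted
        pr$sample_id <- sid
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = pr$chrom, pos = pr$pos, ref = pr$ref, alt = pr$alt,
          af = pr$af, depth = 20L + rpois(nrow(pr), 40),
          sample_id = sid, molecule = molecule, type = "SNV",
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, chrom = pr$chrom, pos = pr$pos, ref = pr$ref,
          alt = pr$alt, af = pr$af, origin = "planted_edit",
          class = NA_character_, zygosity = call_zygosity(pr$af),
          site_id = pr$site_id, type = "SNV", stringsAsFactors = FALSE)
      }
      n_bg <- rpois(1, mean_snvs)
      if (n_bg > 0) {
        cls <- sample(SNV_CLASSES, n_bg, replace = TRUE, prob = spectrum)
        zyg <- sample(names(ZYGOSITY_AF_RANGES), n_bg, replace = TRUE,
                      prob = af_mix)
        for (k in seq_len(n_bg)) {
          from <- substr(cls[k], 1, 1); to <- substr(cls[k], 3, 3)
          pool_name <- if (from == "C") "CG" else "TA"
          repeat {
            ch <- sample(names(genome), 1, prob = chrom_w)
            pool <- base_index[[ch]][[pool_name]]
            if (length(pool) == 0) next
            pos1 <- pool[sample.int(length(pool), 1)]
            if (!in_avoid(ch, pos1)) break
          }
          base <- substr(genome[[ch]], pos1, pos1)
          if (base == from) { ref <- from; alt <- to }
          else { ref <- complement_base(from); alt <- complement_base(to) }
          rng <- ZYGOSITY_AF_RANGES[[zyg[k]]]
          af <- runif(1, rng[1], rng[2])
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, pos = pos1, ref = ref, alt = alt, af = af,
            depth = 20L + rpois(1, 40), sample_id = sid,
            molecule = molecule, type = "SNV", stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, chrom = ch, pos = pos1, ref = ref, alt = alt,
            af = af, origin = "background", class = cls[k],
            zygosity = zyg[k], site_id = NA_character_, type = "SNV",
            stringsAsFactors = FALSE)
        }
      }
      n_ind <- rpois(1, mean_indels)
      if (n_ind > 0) {
        for (k in seq_len(n_ind)) {
          repeat {
            ch <- sample(names(genome), 1, prob = chrom_w)
            len <- sample.int(3L, 1)
            pos1 <- sample.int(nchar(genome[[ch]]) - len - 1L, 1)
            if (!in_avoid(ch, pos1)) break
          }
          anchor <- substr(genome[[ch]], pos1, pos1)
          if (runif(1) < 0.5) {  # deletion: ref = anchor+deleted, alt = anchor
            ref <- substr(genome[[ch]], pos1, pos1 + len)
            alt <- anchor
          } else {               # insertion
            ref <- anchor
            alt <- paste0(anchor, paste(random_bases(len), collapse = ""))
          }
          zyg <- sample(names(ZYGOSITY_AF_RANGES), 1, prob = af_mix)
          rng <- ZYGOSITY_AF_RANGES[[zyg]]
          af <- runif(1, rng[1], rng[2])
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, pos = pos1, ref = ref, alt = alt, af = af,
            depth = 20L + rpois(1, 40), sample_id = sid,
            molecule = molecule, type = "INDEL", stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, chrom = ch, pos = pos1, ref = ref, alt = alt,
            af = af, origin = "background", class = NA_character_,
            zygosity = zyg, site_id = NA_character_, type = "INDEL",
            stringsAsFactors = FALSE)
        }
      }
      tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), af = numeric(), depth = integer(),
        sample_id = character(), molecule = character(), type = character(),
        stringsAsFactors = FALSE)
      tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
      rownames(tab) <- NULL
      plants[[pl]] <- tab
      names(plants)[pl] <- sid
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
    list(plants = plants, truth = truth_df, seed = as.integer(seed))
  })
}

#' Write a plant variant table as VCF v4.2
#'
#' Minimal single-sample VCF writer: allele frequency in the `AF` INFO field,
#' depth in `DP`.
#'
#' @param tab per-plant data.frame from [simulate_plant_cohort()].
#' @param path output path.
#' @param genome optional genome (named character vector) used to emit
#'   contig header lines.
#' @return `path`, invisibly.
#' @export
write_plant_vcf <- function(tab, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=baseedit")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          nchar(genome)))
  hdr <- c(hdr,
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(tab) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s;DP=%d",
            tab$chrom, tab$pos, tab$ref, tab$alt,
            formatC(tab$af, format = "fg", digits = 6), tab$depth)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plant variant table from VCF
#'
#' Reads a single-sample VCF (via \pkg{vcfR}) into the package's flat variant
#' table. Allele frequency is taken from the `AF` INFO field; if absent it is
#' computed from `AD`-style allele depths; records with neither are dropped
#' and counted in the `n_rejected` attribute. Multi-allelic records are split
#' into one row per ALT.
#'
#' @param path VCF path.
#' @param sample_id sample label (default: file name without extension).
#' @param molecule `"DNA"` or `"RNA"`.
#' @return data.frame in the layout of [simulate_plant_cohort()] tables, with
#'   attribute `n_rejected`.
#' @export
read_plant_vcf <- function(path, sample_id = NULL,
                           molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), depth = integer(),
                      sample_id = character(), molecule = character(),
                      type = character(), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  af_raw <- vcfR::extract.info(v, "AF")
  dp_raw <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ad_raw <- if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    vcfR::extract.gt(v, "AD")[, 1]
  } else rep(NA_character_, nrow(fix))

  rows <- list(); n_rejected <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (!is.na(af_raw[i])) {
      suppressWarnings(as.numeric(strsplit(af_raw[i], ",")[[1]]))
    } else if (!is.na(ad_raw[i])) {
      ad <- suppressWarnings(as.numeric(strsplit(ad_raw[i], ",")[[1]]))
      if (sum(ad) > 0) ad[-1] / sum(ad) else rep(NA_real_, length(alts))
    } else rep(NA_real_, length(alts))
    afs <- rep_len(afs, length(alts))
    for (j in seq_along(alts)) {
      if (is.na(afs[j])) { n_rejected <- n_rejected + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
        alt = alts[j], af = afs[j],
        depth = if (is.na(dp_raw[i])) NA_integer_ else dp_raw[i],
        sample_id = sample_id, molecule = molecule,
        type = if (nchar(fix$REF[i]) == 1 && nchar(alts[j]) == 1) "SNV"
               else "INDEL",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), af = numeric(), depth = integer(),
    sample_id = character(), molecule = character(), type = character(),
    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- n_rejected
  out
}
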