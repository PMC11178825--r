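mk_vars <- function(chrom = "chr1", pos, ref, alt, af = 0.5) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
             af = rep_len(af, length(pos)), stringsAsFactors = FALSE)
}

test_that("intersect_callsets keeps variants shared by every caller", {
  a <- mk_vars(pos = 1:3, ref = "C", alt = "T", af = c(0.1, 0.2, 0.3))
  expect_equal(intersect_callsets(list(a, a)), a)

  b <- mk_vars(pos = 2:4, ref = "C", alt = "T")
  c3 <- mk_vars(pos = 2:3, ref = "C", alt = "T")
  out <- intersect_callsets(list(a, b, c3))
  expect_equal(out$pos, 2:3)
  expect_equal(out$af, c(0.2, 0.3))  # AF from the first callset

  d <- mk_vars(pos = 10:12, ref = "C", alt = "T")
  expect_equal(nrow(intersect_callsets(list(a, d))), 0)
})

test_that("intersection is commutative and idempotent", {
  a <- mk_vars(pos = c(1, 2, 5, 9), ref = "C", alt = "T")
  b <- mk_vars(pos = c(2, 5, 7), ref = "C", alt = "T")
  k <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  expect_setequal(k(intersect_callsets(list(a, b))),
                  k(intersect_callsets(list(b, a))))
  expect_equal(intersect_callsets(list(a, a, a)),
               intersect_callsets(list(a, a)))
  expect_error(intersect_callsets(list(a)), "two callsets")
})

test_that("classify_snv_type collapses purine-anchored pairs", {
  expect_equal(classify_snv_type("C", "T"), "C>T")
  expect_equal(classify_snv_type("G", "A"), "C>T")
  expect_equal(classify_snv_type("A", "C"), "T>G")
  expect_equal(classify_snv_type("A", "G"), "T>C")
  expect_equal(classify_snv_type("T", "C"), "T>C")
  expect_error(classify_snv_type("C", "C"), "differ")
  expect_error(classify_snv_type("C", "N"), "A/C/G/T")
  # complementing every pair leaves classes unchanged
  refs <- c("A", "C", "G", "T", "A", "G")
  alts <- c("G", "A", "T", "G", "T", "C")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(classify_snv_type(refs, alts),
               classify_snv_type(unname(comp[refs]), unname(comp[alts])))
})

test_that("call_zygosity applies strict 0.3/0.7 thresholds", {
  expect_equal(call_zygosity(0.85), "homozygous")
  expect_equal(call_zygosity(0.50), "heterozygous")
  expect_equal(call_zygosity(0.70), "heterozygous")  # boundary falls down
  expect_equal(call_zygosity(0.30), "subclonal")
  expect_equal(call_zygosity(0.1), "subclonal")
  expect_error(call_zygosity(0), "\\(0,1\\]")
  expect_error(call_zygosity(1.2), "\\(0,1\\]")
  expect_error(call_zygosity(0.5, het_threshold = 0.7, hom_threshold = 0.3),
               "below")
})

test_that("per_plant_counts tallies classes, indels and chromosomes", {
  empty <- mk_vars(pos = integer(), ref = character(), alt = character())
  tab <- mk_vars(pos = c(10, 20, 30), ref = c("C", "G", "A"),
                 alt = c("T", "A", "G"))
  tab2 <- rbind(tab, data.frame(chrom = "chr2", pos = 5, ref = "CAT",
                                alt = "C", af = 0.5))
  res <- per_plant_counts(list(p0 = empty, p1 = tab, p2 = tab2))
  pp <- res$per_plant
  expect_equal(pp$n_snvs, c(0, 3, 3))
  expect_equal(pp$n_indels, c(0, 0, 1))
  expect_equal(pp[["C>T"]], c(0, 2, 2))  # C>T and G>A collapse
  expect_equal(pp[["T>C"]], c(0, 1, 1))  # A>G collapses
  # class counts partition the SNV total
  cls <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")
  expect_equal(rowSums(pp[, cls]), pp$n_snvs, ignore_attr = TRUE)
})

test_that("germline_fraction matches the hand count", {
  plant <- mk_vars(pos = 1:4, ref = "C", alt = "T",
                   af = c(0.1, 0.5, 0.8, 0.9))
  expect_equal(germline_fraction(plant), 0.75)
  expect_equal(germline_fraction(mk_vars(pos = 1:3, ref = "C", alt = "T",
                                         af = c(0.05, 0.2, 0.3))), 0)
  expect_equal(germline_fraction(mk_vars(pos = 1:2, ref = "C", alt = "T",
                                         af = c(0.8, 0.95))), 1)
  expect_error(germline_fraction(mk_vars(pos = integer(), ref = character(),
                                         alt = character())), "undefined")
})

test_that("zygosity partition holds for arbitrary cohorts", {
  g <- make_toy_genome(1, 30000, seed = 31)
  co <- simulate_plant_cohort(g, NULL, list(mean_snvs = 120), n_plants = 4,
                              seed = 32)
  for (tab in co$plants) {
    z <- table(factor(call_zygosity(tab$af),
                      levels = c("subclonal", "heterozygous", "homozygous")))
    expect_equal(sum(z), nrow(tab))
  }
})

test_that("on_target_genotype_matrix applies the AF rules per cell", {
  g <- make_toy_genome(1, 10000, seed = 21)
  pl <- data.frame(chrom = "chr1", offset = c(1000, 3000, 5000, 7000),
                   strand = "+", n_mismatches = 0)
  res <- plant_candidate_sites(g, FIX_PROTO, pl, "NGG", seed = 22)
  sites <- cbind(res$registry, site_id = paste0("t", 1:4))
  # position 5 of FIX_PROTO is C; AFs chosen per class; site t4 untouched
  es <- data.frame(site_id = c("t1", "t2", "t3"), chrom = "chr1",
                   start = res$registry$start[1:3], strand = "+",
                   position = 5, conversion = "C>T",
                   af = c(0.9, 0.4, 0.1))
  co <- simulate_plant_cohort(res$genome, es, list(mean_snvs = 0),
                              n_plants = 2, seed = 23)
  m <- on_target_genotype_matrix(co$plants, sites, "C>T")
  expect_equal(dim(m), c(2, 4))
  expect_true(all(m[, "t1"] == "biallelic"))
  expect_true(all(m[, "t2"] == "edited"))
  expect_true(all(m[, "t3"] == "unedited"))  # subclonal AF stays unedited
  expect_true(all(m[, "t4"] == "unedited"))
  # the A>G matrix sees none of these C>T edits
  m2 <- on_target_genotype_matrix(co$plants, sites, "A>G")
  expect_true(all(m2 == "unedited"))
})

test_that("motif_context computes frequencies and information content", {
  # genome built so every C>T SNV context is TCG
  chrom <- paste0(strrep("A", 1000), paste(rep("TCG", 50), collapse = ""),
                  strrep("A", 1000))
  g <- c(chr1 = chrom)
  pos <- 1000 + 3 * (0:49) + 2   # the C of each TCG triplet
  snvs <- mk_vars(pos = pos, ref = "C", alt = "T")
  mm <- motif_context(snvs, g, "C>T")
  expect_equal(mm$n_used, 50)
  expect_equal(unname(mm$freq[2, "C"]), 1)
  expect_equal(unname(mm$information), c(2, 2, 2))

  # G>A records are reported on the complementary strand: context of the
  # complement strand of NGN reads C at position 2
  snvs_g <- mk_vars(pos = 1000 + 3 * (0:49) + 3, ref = "G", alt = "A")
  mm2 <- motif_context(snvs_g, g, "C>T")
  expect_equal(unname(mm2$freq[2, "C"]), 1)

  # equal A/C/G/T at a position gives 0 bits; a 50/50 split gives 1 bit
  chrom3 <- paste0("A", paste(vapply(0:39, function(i)
    paste0(c("A", "C", "G", "T")[(i %% 4) + 1], "C",
           c("A", "C")[(i %% 2) + 1]), character(1)), collapse = ""), "A")
  g3 <- c(chr1 = chrom3)
  pos3 <- 1 + 3 * (0:39) + 2
  mm3 <- motif_context(mk_vars(pos = pos3, ref = "C", alt = "T"), g3, "C>T")
  expect_equal(unname(mm3$information[1]), 0)
  expect_equal(unname(mm3$information[3]), 1)
  expect_true(all(mm3$information >= 0 & mm3$information <= 2))
})

test_that("motif_context skips chromosome-edge records and counts them", {
  g <- c(chr1 = paste0("C", strrep("A", 20), "TCG", strrep("A", 20), "C"))
  # edge records at both chromosome ends plus one interior TCG context
  snvs <- mk_vars(pos = c(1, 23, 45), ref = "C", alt = "T")
  mm <- motif_context(snvs, g, "C>T")
  expect_equal(mm$n_used, 1)
  expect_equal(mm$n_skipped, 2)
  expect_equal(unname(mm$freq[2, "C"]), 1)
})

test_that("RNA-mode tables reuse the DNA operations unchanged", {
  g <- make_toy_genome(1, 20000, seed = 91)
  co <- simulate_plant_cohort(g, NULL, list(mean_snvs = 60), n_plants = 2,
                              seed = 92, molecule = "RNA")
  expect_true(all(co$plants[[1]]$molecule == "RNA"))
  counts <- per_plant_counts(co$plants)
  expect_equal(sum(counts$per_plant$n_snvs),
               sum(vapply(co$plants, nrow, numeric(1))))
  expect_true(is.numeric(germline_fraction(co$plants[[1]])))
})
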