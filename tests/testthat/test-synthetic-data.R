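test_that("editing_profile validates probabilities and positions", {
  p <- editing_profile(c_to_t = c(`5` = 0.4), a_to_g = c(`7` = 0.2))
  expect_s3_class(p, "EditingProfile")
  expect_equal(unname(p$c_to_t[5]), 0.4)
  expect_equal(sum(p$c_to_t > 0), 1)
  expect_error(editing_profile(c_to_t = c(`21` = 0.5)), "1\\.\\.20")
  expect_error(editing_profile(c_to_t = c(`5` = 1.2)), "\\[0,1\\]")
  expect_error(editing_profile(c_to_t = c(`5` = 0.7), c_to_g = c(`5` = 0.5)),
               "exceeds 1")
  expect_error(editing_profile(indel_rate = 2), "probability")
})

test_that("make_target_site is deterministic, seed-sensitive and length-exact", {
  s1 <- make_target_site(1, 250, "NGG")
  s1b <- make_target_site(1, 250, "NGG")
  s2 <- make_target_site(2, 250, "NGG")
  expect_identical(s1$amplicon, s1b$amplicon)
  expect_identical(s1$protospacer, s1b$protospacer)
  expect_false(s1$amplicon == s2$amplicon)
  expect_equal(nchar(s1$amplicon), 250)
  # protospacer occurs exactly once and is followed by an NGG PAM
  expect_equal(s1$offset,
               as.integer(regexpr(s1$protospacer, s1$amplicon, fixed = TRUE)) - 1L)
  pam <- substr(s1$amplicon, s1$offset + 21, s1$offset + 23)
  expect_true(pam_match(pam, "NGG"))
  # minimal amplicon: 40 bases still contain the full 23-nt block
  s3 <- make_target_site(3, 40, "NGG")
  expect_equal(nchar(s3$amplicon), 40)
  expect_true(grepl(s3$protospacer, s3$amplicon, fixed = TRUE))
})

test_that("simulate_amplicon_reads honors degenerate and certain profiles", {
  site <- fix_site(1)
  zero <- editing_profile()
  sim <- simulate_amplicon_reads(site, zero, 50, seed = 9)
  expect_true(all(sim$reads == site$amplicon))
  expect_true(all(sim$truth$per_read$class == "WT"))

  certain <- editing_profile(c_to_t = c(`5` = 1))
  sim2 <- simulate_amplicon_reads(site, certain, 50, seed = 9)
  expect_true(all(sim2$truth$per_read$class == "C_TO_T"))
  expect_true(all(sim2$truth$per_read$edits == "5:C>T"))
  edited_amp <- site$amplicon
  substr(edited_amp, site$offset + 5, site$offset + 5) <- "T"
  expect_true(all(sim2$reads == edited_amp))
})

test_that("simulate_amplicon_reads rejects inadmissible conversion positions", {
  site <- fix_site(1)  # position 1 is G
  bad <- editing_profile(c_to_t = c(`1` = 0.5))
  expect_error(simulate_amplicon_reads(site, bad, 10, seed = 1), "position")
})

test_that("simulated conversion rates match generating probabilities", {
  site <- fix_site(1)
  prof <- editing_profile(c_to_t = c(`5` = 0.5))
  sim <- simulate_amplicon_reads(site, prof, 10000, seed = 4)
  frac <- mean(grepl("5:C>T", sim$truth$per_read$edits, fixed = TRUE))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("linked co-occurrence activates window conversions jointly", {
  site <- fix_site(1)  # C at 5, A at 4
  prof <- editing_profile(c_to_t = c(`5` = 0.4), a_to_g = c(`4` = 0.4),
                          cooccurrence = "linked")
  sim <- simulate_amplicon_reads(site, prof, 4000, seed = 8)
  e5 <- grepl("5:C>T", sim$truth$per_read$edits, fixed = TRUE)
  e4 <- grepl("4:A>G", sim$truth$per_read$edits, fixed = TRUE)
  # same probability + one shared draw => identical event sets
  expect_identical(e4, e5)
  # marginal rate preserved
  expect_lt(abs(mean(e4) - 0.4), 4 * sqrt(0.4 * 0.6 / 4000))
})

test_that("indels change read length and are anchored in the protospacer", {
  site <- fix_site(1)
  prof <- editing_profile(indel_rate = 1)
  sim <- simulate_amplicon_reads(site, prof, 30, seed = 5)
  expect_true(all(sim$truth$per_read$class == "INDEL"))
  expect_true(all(nchar(sim$reads) != nchar(site$amplicon)))
  expect_true(all(abs(nchar(sim$reads) - nchar(site$amplicon)) <= 5))
})

test_that("simulation is byte-identical under a fixed seed", {
  site <- fix_site(2)
  prof <- editing_profile(c_to_t = c(`5` = 0.3), indel_rate = 0.02,
                          seq_error_rate = 0.01)
  s1 <- simulate_amplicon_reads(site, prof, 500, seed = 77)
  s2 <- simulate_amplicon_reads(site, prof, 500, seed = 77)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$per_read, s2$truth$per_read)
})

test_that("make_toy_genome has the right shape, determinism and composition", {
  g <- make_toy_genome(2, 50000, seed = 7)
  expect_named(g, c("chr1", "chr2"))
  expect_true(all(nchar(g) == 50000))
  expect_identical(g, make_toy_genome(2, 50000, seed = 7))
  comp <- table(strsplit(g[["chr1"]], "")[[1]]) / 50000
  expect_true(all(abs(comp - 0.25) < 3 * sqrt(0.25 * 0.75 / 50000)))
  expect_error(make_toy_genome(1, 10, seed = 1), ">= 1000")
})

test_that("plant_candidate_sites writes exact, strand-resolved sequences", {
  g <- make_toy_genome(1, 20000, seed = 3)
  proto <- FIX_PROTO
  pl <- data.frame(chrom = "chr1", offset = c(500, 3000, 7000),
                   strand = c("+", "-", "+"), n_mismatches = c(0, 0, 3))
  res <- plant_candidate_sites(g, proto, pl, "NGG", seed = 11)
  reg <- res$registry
  # exact + strand: genome substring equals protospacer, PAM matches
  s1 <- substr(res$genome[["chr1"]], reg$start[1] + 1, reg$end[1])
  expect_identical(s1, proto)
  expect_true(pam_match(substr(res$genome[["chr1"]], reg$end[1] + 1,
                               reg$end[1] + 3), "NGG"))
  # minus strand: reverse complement of protospacer+PAM at the offset
  block2 <- substr(res$genome[["chr1"]], pl$offset[2] + 1, pl$offset[2] + 23)
  expect_identical(revcomp(block2),
                   paste0(reg$planted_seq[2], reg$pam[2]))
  expect_identical(reg$planted_seq[2], proto)
  # 3 mismatches: exhaustive Hamming count
  s3 <- substr(res$genome[["chr1"]], reg$start[3] + 1, reg$end[3])
  expect_equal(sum(strsplit(s3, "")[[1]] != strsplit(proto, "")[[1]]), 3)
})

test_that("plant_candidate_sites rejects overlaps and out-of-bounds placements", {
  g <- make_toy_genome(1, 2000, seed = 3)
  expect_error(plant_candidate_sites(
    g, FIX_PROTO,
    data.frame(chrom = "chr1", offset = c(100, 110), strand = "+",
               n_mismatches = 0)), "overlap")
  expect_error(plant_candidate_sites(
    g, FIX_PROTO,
    data.frame(chrom = "chr1", offset = 1990, strand = "+",
               n_mismatches = 0)), "bounds")
})

test_that("simulate_plant_cohort plants edits with strand-resolved alleles", {
  g <- make_toy_genome(1, 5000, seed = 2)
  pl <- data.frame(chrom = "chr1", offset = c(1000, 3000),
                   strand = c("+", "-"), n_mismatches = 0)
  res <- plant_candidate_sites(g, FIX_PROTO, pl, "NGG", seed = 5)
  reg <- res$registry
  es <- data.frame(site_id = c("a", "b"), chrom = "chr1",
                   start = reg$start, strand = reg$strand,
                   position = 5, conversion = "C>T", af = 0.9)
  co <- simulate_plant_cohort(res$genome, es,
                              background = list(mean_snvs = 0),
                              n_plants = 1, seed = 6)
  tab <- co$plants[[1]]
  expect_equal(nrow(tab), 2)
  plus <- tab[tab$pos == reg$start[1] + 5, ]
  expect_equal(plus$ref, "C"); expect_equal(plus$alt, "T")
  # minus-strand site: C>T specified on the protospacer strand lands as G>A
  minus <- tab[tab$pos == reg$start[2] + 20 - 5 + 1, ]
  expect_equal(minus$ref, "G"); expect_equal(minus$alt, "A")
})

test_that("a single planted edit with zero background yields one record", {
  g <- make_toy_genome(1, 5000, seed = 2)
  res <- plant_candidate_sites(
    g, FIX_PROTO, data.frame(chrom = "chr1", offset = 1000, strand = "+",
                             n_mismatches = 0), "NGG", seed = 5)
  es <- data.frame(site_id = "a", chrom = "chr1", start = res$registry$start,
                   strand = "+", position = 5, conversion = "C>T", af = 0.9)
  co <- simulate_plant_cohort(res$genome, es, list(mean_snvs = 0),
                              n_plants = 1, seed = 1)
  expect_equal(nrow(co$plants[[1]]), 1)
})

test_that("planted edits inconsistent with the reference are rejected", {
  g <- make_toy_genome(1, 5000, seed = 2)
  res <- plant_candidate_sites(
    g, FIX_PROTO, data.frame(chrom = "chr1", offset = 1000, strand = "+",
                             n_mismatches = 0), "NGG", seed = 5)
  # position 4 of FIX_PROTO is A, so C>T there contradicts the genome
  es <- data.frame(site_id = "a", chrom = "chr1", start = res$registry$start,
                   strand = "+", position = 4, conversion = "C>T", af = 0.9)
  expect_error(simulate_plant_cohort(res$genome, es, list(mean_snvs = 0),
                                     n_plants = 1, seed = 1), "inconsistent")
})

test_that("background SNV counts follow the Poisson model", {
  g <- make_toy_genome(1, 50000, seed = 2)
  co <- simulate_plant_cohort(g, NULL, list(mean_snvs = 200),
                              n_plants = 10, seed = 3)
  counts <- vapply(co$plants, nrow, numeric(1))
  band <- qpois(c(0.005, 0.995), 200)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("cohort truth closure: tables reproducible from (spec, seed)", {
  g <- make_toy_genome(1, 20000, seed = 2)
  a <- simulate_plant_cohort(g, NULL, list(mean_snvs = 40, mean_indels = 5),
                             n_plants = 3, seed = 12)
  b <- simulate_plant_cohort(g, NULL, list(mean_snvs = 40, mean_indels = 5),
                             n_plants = 3, seed = 12)
  expect_identical(a$plants, b$plants)
  expect_identical(a$truth, b$truth)
  # truth rows and table rows agree one-to-one
  expect_equal(sum(vapply(a$plants, nrow, numeric(1))), nrow(a$truth))
})

test_that("FASTA/FASTQ/sites-TSV/VCF round trips preserve content", {
  dir <- withr::local_tempdir()
  g <- make_toy_genome(1, 1000, seed = 1)
  fa <- file.path(dir, "g.fa")
  write_genome_fasta(g, fa)
  expect_identical(read_genome_fasta(fa), g)

  site <- fix_site(1)
  sim <- simulate_amplicon_reads(site, editing_profile(), 10, seed = 1)
  fq <- file.path(dir, "r.fastq")
  write_reads_fastq(sim$reads, fq)
  expect_identical(read_reads_fastq(fq), sim$reads)

  tsv <- file.path(dir, "sites.tsv")
  write_sites_tsv(list(site), tsv)
  back <- read_sites_tsv(tsv)[[1]]
  expect_identical(back$amplicon, site$amplicon)
  expect_identical(back$offset, site$offset)

  co <- simulate_plant_cohort(g, NULL, list(mean_snvs = 20, mean_indels = 3),
                              n_plants = 1, seed = 4)
  vcf <- file.path(dir, "p.vcf")
  write_plant_vcf(co$plants[[1]], vcf, genome = g)
  tab <- read_plant_vcf(vcf, sample_id = "plant001")
  expect_equal(nrow(tab), nrow(co$plants[[1]]))
  expect_equal(tab$pos, co$plants[[1]]$pos)
  expect_equal(tab$af, co$plants[[1]]$af, tolerance = 1e-5)
  expect_equal(attr(tab, "n_rejected"), 0L)
})
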