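test_that("variable region is recovered at the best anchor placement", {
  d <- x5yx5_design()
  region <- strrep("A", 33)
  read <- paste0(d$left_anchor_nt, region, d$right_anchor_nt)
  hit <- extract_variable_region(read, NULL, d)
  expect_equal(hit$region, region)
  expect_equal(hit$mismatches, 0)

  # six substitutions across both anchors exceed the combined budget
  withr::with_seed(1, {
    la <- mutate_bases(d$left_anchor_nt, 3)
    ra <- mutate_bases(d$right_anchor_nt, 3)
  })
  expect_null(extract_variable_region(paste0(la, region, ra), NULL, d))

  # shifted read with 2 mismatches in the left anchor: compare against a
  # brute-force scan over every placement
  withr::with_seed(2, la2 <- mutate_bases(d$left_anchor_nt, 2))
  region2 <- paste(sample(c("A", "C", "G", "T"), 33, TRUE), collapse = "")
  read2 <- paste0("GG", la2, region2, d$right_anchor_nt, "TT")
  brute <- function(read) {
    n <- nchar(read)
    span <- nchar(d$left_anchor_nt) + 33 + nchar(d$right_anchor_nt)
    best <- NULL
    best_mm <- Inf
    for (o in seq_len(n - span + 1)) {
      mm <- sum(strsplit(substr(read, o, o + nchar(d$left_anchor_nt) - 1), "")[[1]] !=
                  strsplit(d$left_anchor_nt, "")[[1]]) +
        sum(strsplit(substr(read, o + nchar(d$left_anchor_nt) + 33,
                            o + span - 1), "")[[1]] !=
              strsplit(d$right_anchor_nt, "")[[1]])
      if (mm < best_mm) {
        best_mm <- mm
        best <- substr(read, o + nchar(d$left_anchor_nt),
                       o + nchar(d$left_anchor_nt) + 32)
      }
    }
    list(region = best, mm = best_mm)
  }
  b <- brute(read2)
  expect_lte(b$mm, 5)
  expect_equal(extract_variable_region(read2, NULL, d)$region, b$region)
  expect_equal(extract_variable_region(read2, NULL, d)$region, region2)

  # too-short read signals an unusable read, not an error
  expect_null(extract_variable_region("ACGT", NULL, d))
})

test_that("anchor scan is invariant to non-anchor padding", {
  d <- x5yx5_design()
  withr::with_seed(3, region <- clean_region(d))
  for (pad in c("", "T", "GATTACA")) {
    read <- paste0(pad, d$left_anchor_nt, region, d$right_anchor_nt, pad)
    expect_equal(extract_variable_region(read, NULL, d)$region, region)
  }
})

test_that("filter_translate applies PHRED, codon-model, stop and fixed filters", {
  dx11 <- x11_design()
  d <- x5yx5_design()
  region <- strrep("GCC", 11)
  q30 <- rep(30L, 33)
  expect_equal(filter_translate(region, q30, dx11), strrep("A", 11))

  # a single base below the PHRED threshold discards the read
  q <- q30; q[17] <- 19L
  expect_true(is.na(filter_translate(region, q, dx11)))
  expect_equal(filter_translate(region, q, dx11, min_phred = 19), strrep("A", 11))

  # NNS violation (third base not C/G), N base, stop codon, fixed mismatch
  expect_true(is.na(filter_translate(paste0("GCA", strrep("GCC", 10)), q30, dx11)))
  expect_true(is.na(filter_translate(paste0("NCC", strrep("GCC", 10)), q30, dx11)))
  stopreg <- paste0(strrep("GCC", 5), "TAG", strrep("GCC", 5))
  expect_true(is.na(filter_translate(stopreg, q30, dx11)))
  # codon 6 = TTC translates to F, violating the fixed central Y
  fviol <- paste0(strrep("GCC", 5), "TTC", strrep("GCC", 5))
  expect_true(is.na(filter_translate(fviol, q30, d)))
  fok <- paste0(strrep("GCC", 5), "TAC", strrep("GCC", 5))
  expect_equal(filter_translate(fok, q30, d), "AAAAAYAAAAA")

  # deterministic
  expect_identical(filter_translate(fok, q30, d), filter_translate(fok, q30, d))
})

test_that("process_reads tracks per-stage survivors and FASTQ round-trips", {
  d <- x5yx5_design()
  reads <- make_read_fixture(d, n = c(clean = 30, mm5 = 5, mm6 = 8, lowq = 6,
                                      stop = 4, fixedviol = 5), seed = 9)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_merged_fastq(path)
  expect_equal(nrow(back), nrow(reads))
  expect_equal(back$dna, reads$dna)
  expect_equal(back$quality, reads$quality)

  out <- process_reads(back, d)
  stats <- filter_stats(out)
  expect_equal(stats$reads, c(58, 50, 44, 35))
  expect_equal(nrow(out), 35)
  expect_true(all(substr(out$peptide, 6, 6) == "Y"))
})

test_that("count tables preserve multiset counts exactly", {
  tab <- build_count_table(c("AY", "AY", "AY"), c("AY", "CY", "CY"))
  expect_equal(tab$sequence, c("AY", "CY"))
  expect_equal(tab$input, c(3L, 0L))
  expect_equal(tab$bound, c(1L, 2L))
  expect_equal(total_reads(tab), 6L)

  # empty bound multiset
  tab2 <- build_count_table(c("AA", "AB"), character())
  expect_equal(tab2$bound, c(0L, 0L))

  expect_error(build_count_table(c("AY", "AYA")), "mixed length")

  # count conservation on a larger random multiset
  withr::with_seed(5, {
    inp <- sample(random_peptides(500, 5), 10000, replace = TRUE)
    bnd <- sample(random_peptides(400, 5), 8000, replace = TRUE)
  })
  tab3 <- build_count_table(inp, bnd)
  expect_equal(nrow(tab3), length(unique(c(inp, bnd))))
  expect_equal(sum(tab3$input), 10000L)
  expect_equal(sum(tab3$bound), 8000L)
})

test_that("count tables round-trip through TSV", {
  tab <- build_count_table(c("AY", "AY", "CY"), c("CY"), round_label = "R2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(round_label(back), "R2")
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("subsampling is a seeded hypergeometric thinning", {
  withr::with_seed(8, tab <- build_count_table(
    sample(random_peptides(50, 4), 2000, replace = TRUE),
    sample(random_peptides(50, 4), 2000, replace = TRUE)))
  # full depth is the identity
  same <- subsample_table(tab, 2000, seed = 1)
  expect_equal(as.data.frame(same), as.data.frame(tab))
  # reproducible given the seed
  expect_equal(as.data.frame(subsample_table(tab, 500, seed = 3)),
               as.data.frame(subsample_table(tab, 500, seed = 3)))
  # depth zero empties the table (all-zero rows are dropped)
  expect_equal(nrow(subsample_table(tab, 0, seed = 1)), 0L)
  expect_error(subsample_table(tab, 10000, seed = 1), "depth exceeds")

  # hypergeometric expectation: a 50/50 two-sequence column subsampled to
  # half depth keeps fraction 0.5 on average (tolerance 3 standard errors)
  tab5050 <- pepbound:::new_count_table(c("AAAA", "CCCC"), c(100L, 100L),
                                        c(100L, 100L))
  fr <- vapply(1:400, function(s) subsample_table(tab5050, 100, seed = s)$input[1] / 100,
               numeric(1))
  # per-draw variance of a hypergeometric fraction: n=100, K=100, N=200
  se <- sqrt(100 * 0.5 * 0.5 * (200 - 100) / (200 - 1)) / 100 / sqrt(400)
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 1e-12)

  # expected counts scale linearly with depth
  m1 <- mean(vapply(1:200, function(s) subsample_table(tab5050, 40, seed = s)$input[1], numeric(1)))
  m2 <- mean(vapply(1:200, function(s) subsample_table(tab5050, 80, seed = s)$input[1], numeric(1)))
  expect_lt(abs(m2 / m1 - 2), 0.15)
})
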