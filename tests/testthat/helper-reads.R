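# Programmatic FASTQ fixture: reads with planted anchor mismatches, low-PHRED
# bases, stop codons and fixed-position violations, in known numbers, so
# survivor counts at each processing stage are exact by construction.

BASES <- c("A", "C", "G", "T")

nns_sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), c("C", "G"), paste0))
  setdiff(all, "TAG")
}

# Codons for one valid region (fixed positions honoured; Y -> TAC under NNS).
clean_region <- function(design) {
  codons <- sample(nns_sense_codons(), design$var_len_aa, replace = TRUE)
  fp <- design$fixed_positions
  if (!is.null(fp)) {
    stopifnot(all(fp == "Y"))
    codons[as.integer(names(fp))] <- "TAC"
  }
  paste(codons, collapse = "")
}

mutate_bases <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# Build the fixture. Categories and their fate:
#   clean      pass everything
#   mm5        5 combined anchor mismatches: extraction still succeeds
#   mm6        6 combined anchor mismatches: extraction fails
#   lowq       one region base at PHRED 19: quality filter fails
#   stop       one TAG codon planted: translation fails
#   fixedviol  central codon is TTC (Phe): library-design filter fails
make_read_fixture <- function(design,
                              n = c(clean = 600, mm5 = 80, mm6 = 100,
                                    lowq = 80, stop = 70, fixedviol = 70),
                              seed = 42) {
  withr::with_seed(seed, {
    la <- design$left_anchor_nt
    ra <- design$right_anchor_nt
    rows <- list()
    add <- function(category, region, la_mm = 0, ra_mm = 0, low_q = FALSE,
                    pad = TRUE) {
      l <- if (la_mm > 0) mutate_bases(la, la_mm) else la
      r <- if (ra_mm > 0) mutate_bases(ra, ra_mm) else ra
      pre <- if (pad) paste(sample(BASES, sample(0:5, 1), TRUE), collapse = "") else ""
      post <- if (pad) paste(sample(BASES, sample(0:5, 1), TRUE), collapse = "") else ""
      dna <- paste0(pre, l, region, r, post)
      qual <- sample(25:40, nchar(dna), replace = TRUE)
      if (low_q) {
        at <- nchar(pre) + nchar(l) + sample(design$var_len_nt, 1)
        qual[at] <- 19L
      }
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        category = category, dna = dna, quality = list(qual))
    }
    for (i in seq_len(n[["clean"]])) add("clean", clean_region(design))
    for (i in seq_len(n[["mm5"]]))
      add("mm5", clean_region(design), la_mm = 3, ra_mm = 2, pad = FALSE)
    for (i in seq_len(n[["mm6"]]))
      add("mm6", clean_region(design), la_mm = 3, ra_mm = 3, pad = FALSE)
    for (i in seq_len(n[["lowq"]])) add("lowq", clean_region(design), low_q = TRUE)
    for (i in seq_len(n[["stop"]])) {
      region <- clean_region(design)
      fixed <- as.integer(names(design$fixed_positions))
      at <- sample(setdiff(seq_len(design$var_len_aa), fixed), 1)
      substr(region, 3 * at - 2, 3 * at) <- "TAG"
      add("stop", region)
    }
    for (i in seq_len(n[["fixedviol"]])) {
      region <- clean_region(design)
      at <- as.integer(names(design$fixed_positions))[1]
      substr(region, 3 * at - 2, 3 * at) <- "TTC"
      add("fixedviol", region)
    }
    out <- dplyr::bind_rows(rows)
    out$read_id <- sprintf("read%04d_%s", seq_len(nrow(out)), out$category)
    out[sample(nrow(out)), c("read_id", "dna", "quality", "category")]
  })
}

write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]),
                 reads$dna[i],
                 "+",
                 rawToChar(as.raw(reads$quality[[i]] + 33L))), con)
  }
  invisible(path)
}
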