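#' Read merged amplicon reads from a FASTQ file
#'
#' Reads Sanger-encoded (PHRED+33) FASTQ of pre-merged read pairs. Pair
#' merging itself is out of scope; the pipeline consumes merged or single-end
#' reads.
#'
#' @param path FASTQ file path (uncompressed or gzipped).
#' @return A tibble with columns `read_id`, `dna` (character) and `quality`
#'   (list column of integer PHRED scores, one per base).
#' @export
read_merged_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- as(Biostrings::quality(x), "IntegerList")
  tibble(read_id = unname(names(x)),
         dna = unname(as.character(x)),
         quality = unname(as.list(qual)))
}

# Hamming mismatches between an integer-encoded read slice and anchor.
pb_hamming <- function(read_int, from, anchor_int) {
  sum(read_int[from:(from + length(anchor_int) - 1L)] != anchor_int)
}

#' Locate and crop the variable region of one merged read
#'
#' Scans all placements of the constant left/right nucleotide anchors around a
#' variable region of the designed length and returns the region under the
#' placement with the fewest combined anchor mismatches, provided that number
#' does not exceed `max_mismatch`. Ties are broken towards the leftmost
#' placement. The mismatch budget is shared across both anchors.
#'
#' @param dna Nucleotide string of the merged read.
#' @param quality Integer PHRED scores, same length as `dna`, or `NULL`.
#' @param design A [library_design()].
#' @param max_mismatch Maximum combined Hamming mismatches over both anchors.
#' @return A list with `region` (nucleotide string), `quality` (integer vector
#'   or `NULL`) and `mismatches`, or `NULL` when no placement qualifies (this
#'   includes reads shorter than anchors + region).
#' @examples
#' d <- x5yx5_design()
#' read <- paste0(d$left_anchor_nt, strrep("A", 33), d$right_anchor_nt)
#' extract_variable_region(read, NULL, d)$region
#' @export
extract_variable_region <- function(dna, quality = NULL, design, max_mismatch = 5L) {
  stopifnot(max_mismatch >= 0L)
  la <- utf8ToInt(design$left_anchor_nt)
  ra <- utf8ToInt(design$right_anchor_nt)
  vn <- design$var_len_nt
  ri <- utf8ToInt(dna)
  total <- length(la) + vn + length(ra)
  if (length(ri) < total) return(NULL)
  starts <- seq_len(length(ri) - total + 1L)
  best_mm <- Inf
  best_at <- NA_integer_
  for (o in starts) {
    mm <- pb_hamming(ri, o, la)
    if (mm >= best_mm) next
    mm <- mm + pb_hamming(ri, o + length(la) + vn, ra)
    if (mm < best_mm) {
      best_mm <- mm
      best_at <- o
    }
  }
  if (!is.finite(best_mm) || best_mm > max_mismatch) return(NULL)
  from <- best_at + length(la)
  list(region = substr(dna, from, from + vn - 1L),
       quality = if (!is.null(quality)) quality[from:(from + vn - 1L)],
       mismatches = best_mm)
}

# Translate a cropped variable region, enforcing the codon model, absence of
# stop codons, and fixed library positions. Returns NA_character_ on failure.
pb_translate_region <- function(region_nt, design) {
  if (nchar(region_nt) != design$var_len_nt) abort("region length does not match design")
  codons <- substring(region_nt, seq(1L, design$var_len_nt, 3L),
                      seq(3L, design$var_len_nt, 3L))
  if (design$codon_model == "NNS" &&
      !all(substr(codons, 3L, 3L) %in% c("C", "G"))) return(NA_character_)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa) || any(aa == "*")) return(NA_character_)
  fp <- design$fixed_positions
  if (!is.null(fp) && !all(aa[as.integer(names(fp))] == fp)) return(NA_character_)
  paste(aa, collapse = "")
}

#' Quality-filter and translate a cropped variable region
#'
#' Discards the region (returns `NA`) when any base has PHRED below
#' `min_phred`, when any codon violates the design's codon model (including
#' any `N` base), when the translation contains a stop codon, or when a fixed
#' library position does not carry its required residue. Otherwise returns
#' the translated peptide. The PHRED filter applies to the cropped region
#' only, not to the anchors.
#'
#' @param region_nt Nucleotide string of length `design$var_len_nt`.
#' @param region_quality Integer PHRED scores for the region, or `NULL` to
#'   skip the quality filter.
#' @param design A [library_design()].
#' @param min_phred Minimum PHRED score tolerated at every base.
#' @return The peptide string, or `NA_character_`.
#' @export
filter_translate <- function(region_nt, region_quality = NULL, design, min_phred = 20L) {
  if (!is.null(region_quality)) {
    if (length(region_quality) != nchar(region_nt))
      abort("quality length does not match region length")
    if (any(region_quality < min_phred)) return(NA_character_)
  }
  pb_translate_region(region_nt, design)
}

#' Process merged reads into surviving peptides
#'
#' Runs the full read-processing chain: anchor scan and cropping, per-base
#' PHRED filtering of the cropped region, and translation with library-design
#' filtering. Per-stage survivor counts are attached as the `"filter_stats"`
#' attribute and available via [filter_stats()].
#'
#' @param reads Tibble as returned by [read_merged_fastq()] (columns `dna`,
#'   `quality`; `quality` may be absent).
#' @param design A [library_design()].
#' @param min_phred Minimum PHRED score (see [filter_translate()]).
#' @param max_mismatch Combined anchor mismatch budget (see
#'   [extract_variable_region()]).
#' @return Tibble with one row per surviving read: `read_id` (if present),
#'   `peptide`.
#' @export
process_reads <- function(reads, design, min_phred = 20L, max_mismatch = 5L) {
  n <- nrow(reads)
  qual <- if ("quality" %in% names(reads)) reads$quality else rep(list(NULL), n)
  regions <- vector("list", n)
  for (i in seq_len(n))
    regions[[i]] <- extract_variable_region(reads$dna[[i]], qual[[i]],
                                            design, max_mismatch)
  anchored <- !vapply(regions, is.null, logical(1))
  q_ok <- anchored
  for (i in which(anchored)) {
    q <- regions[[i]]$quality
    if (!is.null(q) && any(q < min_phred)) q_ok[i] <- FALSE
  }
  peptide <- rep(NA_character_, n)
  for (i in which(q_ok))
    peptide[i] <- pb_translate_region(regions[[i]]$region, design)
  keep <- !is.na(peptide)
  out <- tibble(peptide = peptide[keep])
  if ("read_id" %in% names(reads)) out <- tibble(read_id = reads$read_id[keep],
                                                 peptide = peptide[keep])
  attr(out, "filter_stats") <- tibble(
    stage = c("input", "anchored", "quality", "translated"),
    reads = c(n, sum(anchored), sum(q_ok), sum(keep)))
  out
}

#' @rdname process_reads
#' @param x Result of [process_reads()].
#' @export
filter_stats <- function(x) attr(x, "filter_stats")
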