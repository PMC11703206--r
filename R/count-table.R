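#' Build a per-round count table from peptide multisets
#'
#' One row per distinct peptide observed in either library, with its read
#' count in the input (pre-selection) and bound (post-selection) sequencing
#' libraries of one selection round.
#'
#' @param input_peptides,bound_peptides Character vectors of observed
#'   peptides (with repetitions; multisets of reads).
#' @param round_label Label of the selection round, e.g. `"R1"`.
#' @return A `pb_count_table`: a tibble with columns `sequence`, `input`,
#'   `bound`, carrying the round label as an attribute.
#' @examples
#' build_count_table(c("AY", "AY", "AY"), c("AY", "CY", "CY"))
#' @export
build_count_table <- function(input_peptides, bound_peptides = character(), round_label = "R1") {
  seqs <- c(input_peptides, bound_peptides)
  if (!length(seqs)) abort("no peptides supplied")
  if (length(unique(nchar(seqs))) != 1L) abort("peptides of mixed length")
  lev <- sort(unique(seqs))
  new_count_table(
    sequence = lev,
    input = tabulate(match(input_peptides, lev), length(lev)),
    bound = tabulate(match(bound_peptides, lev), length(lev)),
    round_label = round_label)
}

new_count_table <- function(sequence, input, bound, round_label = "R1") {
  stopifnot(length(sequence) == length(input), length(input) == length(bound))
  if (any(input < 0) || any(bound < 0)) abort("negative counts")
  keep <- input + bound >= 1L
  out <- tibble(sequence = sequence[keep],
                input = as.integer(input[keep]),
                bound = as.integer(bound[keep]))
  attr(out, "round_label") <- round_label
  class(out) <- c("pb_count_table", class(out))
  out
}

#' @rdname build_count_table
#' @param table A `pb_count_table`.
#' @export
round_label <- function(table) attr(table, "round_label")

#' @rdname build_count_table
#' @export
total_reads <- function(table) sum(table$input) + sum(table$bound)

#' Read or write a count table as tab-separated text
#'
#' The on-disk interchange format is a 3-column TSV (`sequence`, `input`,
#' `bound`) preceded by a `# round=<label>` comment line.
#'
#' @param path File path.
#' @return `read_count_table()` returns a `pb_count_table`;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  label <- if (startsWith(first, "# round=")) sub("^# round=", "", first) else "R1"
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  new_count_table(d$sequence, d$input, d$bound, round_label = label)
}

#' @rdname read_count_table
#' @param table A `pb_count_table`.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# round=", attr(table, "round_label") %||% "R1"), con)
  utils::write.table(as.data.frame(table[c("sequence", "input", "bound")]),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Down-sample one count column without replacement (counted hypergeometric
# scheme): choose `depth` of the `sum(counts)` reads uniformly.
pb_subsample_column <- function(counts, depth) {
  tot <- sum(counts)
  if (depth > tot) abort("requested depth exceeds column total")
  if (depth == tot) return(as.integer(counts))
  cs <- cumsum(as.numeric(counts))
  pos <- sample.int(tot, depth)
  tabulate(findInterval(pos - 0.5, cs) + 1L, nbins = length(counts))
}

#' Down-sample a count table to a fixed sequencing depth
#'
#' Each column (input and bound) is independently down-sampled without
#' replacement to `depth` reads, emulating a shallower sequencing run.
#'
#' @param table A `pb_count_table`.
#' @param depth Target reads per column; must not exceed either column total.
#' @param seed Integer seed making the draw reproducible.
#' @return A `pb_count_table` (rows reduced to zero total counts are dropped).
#' @export
subsample_table <- function(table, depth, seed = NULL) {
  draw <- function() {
    new_count_table(table$sequence,
                    pb_subsample_column(table$input, depth),
                    pb_subsample_column(table$bound, depth),
                    round_label = attr(table, "round_label"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.pb_count_table <- function(x, ...) {
  cat("<count table> round ", attr(x, "round_label") %||% "?",
      ": ", nrow(x), " sequences, ", sum(x$input), " input / ",
      sum(x$bound), " bound reads\n", sep = "")
  NextMethod()
}

#' @export
autoplot.pb_count_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$input + 0.5, y = .data$bound + 0.5)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "input reads + 0.5", y = "bound reads + 0.5",
                  title = paste("Round", attr(object, "round_label") %||% "")) +
    ggplot2::theme_minimal()
}
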