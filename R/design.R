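#' Describe a peptide-display library design
#'
#' A library design records the geometry of the displayed variable region:
#' its length in residues and nucleotides, any fixed residues (e.g. the
#' central tyrosine of an X5-Y-X5 library), the constant amino-acid flanks
#' displayed on either side, and the constant nucleotide anchors used to
#' locate the variable region in merged sequencing reads.
#'
#' @param var_len_aa Length of the variable region in residues.
#' @param fixed_positions Named character vector mapping 1-based variable
#'   region positions to required residues, e.g. `c("6" = "Y")`. `NULL` for a
#'   fully degenerate library.
#' @param left_flank_aa,right_flank_aa Constant displayed residues flanking
#'   the variable region.
#' @param left_anchor_nt,right_anchor_nt Constant nucleotide sequences
#'   flanking the variable region in the amplicon.
#' @param codon_model Degenerate codon scheme of the library; `"NNS"`
#'   restricts the third base of each codon to C or G.
#'
#' @return An object of class `library_design`.
#' @examples
#' x5yx5_design()
#' @export
library_design <- function(var_len_aa = 11L,
                           fixed_positions = NULL,
                           left_flank_aa = "GQSGQ",
                           right_flank_aa = "GGQSG",
                           left_anchor_nt = "GTAGCTGGCCAGTCTGGCCAG",
                           right_anchor_nt = "GGAGGGCAGTCTGGGCAGTC",
                           codon_model = "NNS") {
  var_len_aa <- as.integer(var_len_aa)
  stopifnot(var_len_aa >= 1L, nzchar(left_anchor_nt), nzchar(right_anchor_nt))
  if (!is.null(fixed_positions)) {
    pos <- as.integer(names(fixed_positions))
    if (anyNA(pos) || any(pos < 1L) || any(pos > var_len_aa))
      abort("fixed_positions names must be 1-based positions within the variable region")
    if (!all(fixed_positions %in% PB_ALPHABET))
      abort("fixed_positions values must be single canonical residues")
  }
  structure(
    list(var_len_aa = var_len_aa,
         var_len_nt = 3L * var_len_aa,
         fixed_positions = fixed_positions,
         left_flank_aa = left_flank_aa,
         right_flank_aa = right_flank_aa,
         left_anchor_nt = toupper(left_anchor_nt),
         right_anchor_nt = toupper(right_anchor_nt),
         codon_model = match.arg(codon_model, c("NNS", "NNN"))),
    class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  fixed <- if (is.null(x$fixed_positions)) "none" else
    paste(names(x$fixed_positions), x$fixed_positions, sep = ":", collapse = ", ")
  cat("<library_design> ", x$var_len_aa, "-mer variable region (",
      x$var_len_nt, " nt, ", x$codon_model, ")\n",
      "  fixed positions: ", fixed, "\n",
      "  flanks: ", x$left_flank_aa, " / ", x$right_flank_aa, "\n", sep = "")
  invisible(x)
}

#' Built-in library designs
#'
#' `x5yx5_design()` is an 11-mer library with a fixed central tyrosine between
#' two fully degenerate 5-mers; `x11_design()` is a fully degenerate 11-mer.
#'
#' @return A [library_design()].
#' @export
x5yx5_design <- function() library_design(11L, fixed_positions = c("6" = "Y"))

#' @rdname x5yx5_design
#' @export
x11_design <- function() library_design(11L)

#' Read or write a library design as YAML
#'
#' @param path File path.
#' @return `read_design()` returns a [library_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  fixed <- NULL
  if (length(y$fixed_positions))
    fixed <- setNames(as.character(unlist(y$fixed_positions)),
                      names(y$fixed_positions))
  library_design(var_len_aa = y$var_len_aa,
                 fixed_positions = fixed,
                 left_flank_aa = y$left_flank_aa %||% "GQSGQ",
                 right_flank_aa = y$right_flank_aa %||% "GGQSG",
                 left_anchor_nt = y$left_anchor_nt %||% "GTAGCTGGCCAGTCTGGCCAG",
                 right_anchor_nt = y$right_anchor_nt %||% "GGAGGGCAGTCTGGGCAGTC",
                 codon_model = y$codon_model %||% "NNS")
}

#' @rdname read_design
#' @param design A [library_design()].
#' @export
write_design <- function(design, path) {
  y <- design[c("var_len_aa", "left_flank_aa", "right_flank_aa",
                "left_anchor_nt", "right_anchor_nt", "codon_model")]
  y$fixed_positions <- as.list(design$fixed_positions)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
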