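# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string (ACGTN alphabet).
revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Read a gene list that may be given as a file path or a character vector.
as_gene_list <- function(x) {
  if (is.null(x)) return(character(0))
  if (length(x) == 1 && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  x <- trimws(x)
  unique(x[nzchar(x)])
}

# Coerce a chrom-sizes argument (named numeric, or data.frame / file with
# columns chrom,size) to a named numeric vector.
as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1 &&
      file.exists(chrom_sizes)) {
    chrom_sizes <- read.delim(chrom_sizes, header = FALSE,
                              col.names = c("chrom", "size"))
  }
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                            as.character(chrom_sizes[[1]]))
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be named by chromosome")
  }
  chrom_sizes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
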