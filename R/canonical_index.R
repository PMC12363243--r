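#' Canonical tetranucleotide index
#'
#' Enumerates all 256 tetranucleotides over \{A,C,G,T\} and collapses them
#' into reverse-complement equivalence classes. A 4-mer and its reverse
#' complement occur with identical frequency in double-stranded DNA, so the
#' 256 raw 4-mers reduce to 136 canonical classes: 16 palindromic 4-mers
#' that are their own reverse complement, plus (256 - 16) / 2 = 120 paired
#' classes. The canonical representative of a class is the lexicographic
#' minimum of the 4-mer and its reverse complement, and classes are ordered
#' lexicographically.
#'
#' @return An object of class `canonical_index`: a list with
#'   \describe{
#'     \item{classes}{character vector of the 136 canonical 4-mers, sorted.}
#'     \item{lookup}{named integer vector mapping each of the 256 4-mers to
#'       its position in `classes`.}
#'     \item{palindromic}{logical vector over `classes`; `TRUE` where the
#'       class is its own reverse complement (16 classes).}
#'   }
#' @examples
#' idx <- build_canonical_index()
#' length(idx$classes)            # 136
#' idx$classes[idx$lookup["TTTT"]] # "AAAA"
#' @export
build_canonical_index <- function() {
  if (!is.null(.index_cache$index)) return(.index_cache$index)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b4 = bases, b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  kmers <- sort(paste0(grid$b1, grid$b2, grid$b3, grid$b4))
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  classes <- sort(unique(canon))
  lookup <- match(canon, classes)
  names(lookup) <- kmers
  idx <- structure(
    list(classes = classes,
         lookup = lookup,
         palindromic = classes == revcomp(classes)),
    class = "canonical_index")
  .index_cache$index <- idx
  idx
}

.index_cache <- new.env(parent = emptyenv())

#' @export
print.canonical_index <- function(x, ...) {
  cat("Canonical tetranucleotide index:", length(x$classes), "classes (",
      sum(x$palindromic), "palindromic ) over", length(x$lookup), "4-mers\n")
  invisible(x)
}
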