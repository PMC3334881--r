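# Internal sequence helpers. All coordinates inside the package are
# 0-based, half-open; GFF3 output is converted to 1-based closed.

.BASES <- c("A", "C", "G", "T")

# complement of a DNA/RNA string kept as a string (U treated as T)
.comp <- function(x) chartr("ACGTU", "TGCAA", x)

#' @importFrom Biostrings DNAStringSet reverseComplement
.revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

.rand_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# map an RNA-alphabet sequence to the internal DNA alphabet
.normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

.is_dna <- function(x) !grepl("[^ACGT]", x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# recursive modifyList that only accepts known keys
.merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      .stopf("unknown %s field '%s'", path, nm)
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste(path, nm, sep = "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}
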