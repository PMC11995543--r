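#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.BASES <- c("A", "C", "G", "T")
.PYRIMIDINES <- c("C", "T")
.PURINES <- c("A", "G")

## six pyrimidine-centred substitution classes (SBS convention)
.CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.TRANSITIONS <- c("C>T", "T>C")

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.revcomp <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(x) paste(rev(unname(.COMP[x])), collapse = ""),
         character(1))
}

.check_base <- function(x, what = "base") {
  bad <- !(x %in% .BASES)
  if (any(bad)) .stopf("invalid %s: '%s' (must be one of A, C, G, T)",
                       what, paste(unique(x[bad]), collapse = "', '"))
  invisible(x)
}

.check_count <- function(x, name, min = 0) {
  if (any(!is.finite(x)) || any(x < min))
    .stopf("'%s' must be a finite number >= %s", name, min)
  invisible(x)
}

## Write a data.frame as a TSV with header, deterministic formatting.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "", ...)
}
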