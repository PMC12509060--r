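# Internal numerical helpers.

#' @keywords internal
#' @noRd
.logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a stream-specific 32-bit seed from a master seed. Keeps every
# generator reproducible from one integer while decoupling the streams.
#' @keywords internal
#' @noRd
.deriveSeed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(salt) %% 100003L
}

#' @keywords internal
#' @noRd
.assertScalarNumber <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("'%s' must be > %g", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("'%s' must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

#' Library-type label for genotype/treatment codes
#'
#' Maps the binary genotype code (0 = Bd21, 1 = Bd3-1) and treatment code
#' (0 = control, 1 = drought) onto the conventional library-type labels
#' `Bd21c`, `Bd21d`, `Bd3-1c`, `Bd3-1d`.
#'
#' @param genotype integer vector of 0/1 genotype codes.
#' @param treatment integer vector of 0/1 treatment codes.
#' @return Character vector of library-type labels.
#' @examples
#' libraryTypeLabel(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
libraryTypeLabel <- function(genotype, treatment) {
  stopifnot(all(genotype %in% c(0, 1)), all(treatment %in% c(0, 1)))
  paste0(ifelse(genotype == 0, "Bd21", "Bd3-1"),
         ifelse(treatment == 0, "c", "d"))
}

#' @keywords internal
#' @noRd
.libraryTypes <- function() c("Bd21c", "Bd21d", "Bd3-1c", "Bd3-1d")

# genotype/treatment codes for a library-type label
#' @keywords internal
#' @noRd
.codesForLibraryType <- function(lt) {
  stopifnot(lt %in% .libraryTypes())
  list(genotype = as.integer(grepl("^Bd3-1", lt)),
       treatment = as.integer(grepl("d$", lt)))
}
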