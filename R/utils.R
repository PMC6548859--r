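# Internal helpers shared across modules.

# Run `expr` under a given RNG seed, restoring the caller's RNG state on exit.
# All user-facing stochastic operations take an explicit `seed` and route
# through this, so they are reproducible and leave the global stream untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_invalid(sprintf(
      "`%s` must be a single number in %s%g, %g%s, got %s",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == floor(x)
  if (!ok) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Legal tetraploid dosage codes (reference-allele frequency of AAAA..BBBB).
DOSAGE_CODES <- c(0, 0.25, 0.5, 0.75, 1)

locus_ids <- function(loci) {
  paste0(loci$chrom, ":", loci$pos)
}

# Attach/retrieve the locus table (chrom, pos, ref, alt) carried on genotype
# and read-count matrices.
loci_info <- function(x) {
  lo <- attr(x, "loci", exact = TRUE)
  if (is.null(lo)) stop_invalid("object carries no locus table ('loci' attribute)")
  lo
}

set_loci <- function(x, loci) {
  stopifnot(is.data.frame(loci), all(c("chrom", "pos") %in% names(loci)))
  attr(x, "loci") <- loci
  x
}
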