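#' Write dosages and read counts as a ploidy-4 VCF
#'
#' Genotypes are written as sorted ploidy-4 GT strings (AABB -> `0/0/1/1`;
#' phase is never known here), missing cells as `./././.`, and read counts,
#' when supplied, as the AD field (`ref,alt`). With a `filter_report`, the
#' FILTER column carries the first failing reason for dropped loci and PASS
#' otherwise; without one it is `.`.
#'
#' @param path output path (plain text `.vcf`).
#' @param dosages samples x loci dosage matrix (codes or `NA`), locus table
#'   attached; may be `NULL` if only counts are written.
#' @param counts optional matching `read_counts` for the AD field.
#' @param layout optional [genome_layout()] for contig header lines.
#' @param filter_report optional `filter_report` aligned with the loci.
#' @return the path, invisibly.
#' @export
write_vcf <- function(path, dosages, counts = NULL, layout = NULL,
                      filter_report = NULL) {
  stopifnot(is.matrix(dosages))
  loci <- loci_info(dosages)
  samples <- rownames(dosages)
  n <- length(samples); m <- nrow(loci)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=spudgs",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Tetraploid genotype, sorted alleles\">"
  )
  if (!is.null(counts)) {
    header <- c(header,
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depths for ref,alt\">")
  }
  if (!is.null(layout)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                layout$chromosomes$name,
                                layout$chromosomes$length))
  }
  for (rs in c("depth_fail", "alt_support_fail", "fraction_fail",
               "missing_fail", "maf_fail")) {
    header <- c(header, sprintf(
      "##FILTER=<ID=%s,Description=\"Dropped by the %s rule\">", rs, rs))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))

  gt_of <- function(code) {
    if (is.na(code)) return("./././.")
    n_ref <- round(code * 4)
    paste(c(rep("0", n_ref), rep("1", 4 - n_ref)), collapse = "/")
  }
  filt <- rep(if (is.null(filter_report)) "." else "PASS", m)
  if (!is.null(filter_report)) {
    pl <- filter_report$per_locus
    stopifnot(nrow(pl) == m)
    for (rs in c("depth_fail", "alt_support_fail", "fraction_fail",
                 "missing_fail", "maf_fail")) {
      filt[pl[[rs]]] <- rs
    }
  }
  ref <- if ("ref" %in% names(loci)) loci$ref else rep("A", m)
  alt <- if ("alt" %in% names(loci)) loci$alt else rep("T", m)

  rows <- character(m)
  fmt <- if (is.null(counts)) "GT" else "GT:AD"
  for (i in seq_len(m)) {
    cells <- vapply(seq_len(n), function(s) {
      g <- gt_of(dosages[s, i])
      if (is.null(counts)) g
      else paste0(g, ":", counts$ref[s, i], ",", counts$alt[s, i])
    }, character(1))
    rows[i] <- paste(c(loci$chrom[i], loci$pos[i], locus_ids(loci)[i],
                       ref[i], alt[i], ".", filt[i], ".", fmt, cells),
                     collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a ploidy-4 VCF into dosage and/or read-count matrices
#'
#' GT strings are converted to reference-allele-frequency codes (count of
#' `0` alleles / 4; `0/0/1/1` -> 0.5; `./././.` -> `NA`); AD, when present,
#' is parsed into ref/alt count matrices. Multi-allelic records are skipped
#' with a warning; mixed ploidy is an error.
#'
#' @param path VCF path (plain or gzipped).
#' @return list with `dosages` (matrix or `NULL` when GT absent), `counts`
#'   (a `read_counts` or `NULL` when AD absent), and `loci`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  gt_raw <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                     error = function(e) NULL)
  dosages <- NULL
  if (!is.null(gt_raw)) {
    alleles <- gsub("[|]", "/", gt_raw)
    n_alleles <- lengths(strsplit(alleles, "/"))
    called <- !is.na(alleles) & !grepl("\\.", alleles)
    if (length(unique(n_alleles[called])) > 1) {
      stop_invalid("mixed genotype ploidy in VCF")
    }
    if (any(called) && unique(n_alleles[called]) != 4L) {
      stop_invalid("expected ploidy-4 genotypes")
    }
    n_ref <- vapply(strsplit(alleles, "/"), function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) NA_integer_
      else sum(a == "0")
    }, integer(1))
    code <- matrix(n_ref / 4, nrow(gt_raw), ncol(gt_raw))
    dosages <- t(code)
    dimnames(dosages) <- list(colnames(gt_raw), locus_ids(loci))
    dosages <- set_loci(dosages, loci)
  }
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                     error = function(e) NULL)
  counts <- NULL
  if (!is.null(ad_raw) && !all(is.na(ad_raw))) {
    ref_d <- t(vapply(seq_len(nrow(ad_raw)), function(i) {
      as.integer(sub(",.*", "", ad_raw[i, ]))
    }, integer(ncol(ad_raw))))
    alt_d <- t(vapply(seq_len(nrow(ad_raw)), function(i) {
      as.integer(sub(".*,", "", ad_raw[i, ]))
    }, integer(ncol(ad_raw))))
    ref_m <- t(ref_d); alt_m <- t(alt_d)
    dimnames(ref_m) <- dimnames(alt_m) <- list(colnames(ad_raw),
                                               locus_ids(loci))
    counts <- structure(list(ref = set_loci(ref_m, loci), alt = alt_m,
                             loci = loci), class = "read_counts")
  }
  if (is.null(dosages) && is.null(counts)) {
    stop_invalid("VCF carries neither GT nor AD")
  }
  list(dosages = dosages, counts = counts, loci = loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phenotype CSV
#'
#' Expects a `sample_id` column plus numeric trait columns; blank cells are
#' missing. Traits phenotyped in fewer than `min_phenotyped` of samples are
#' dropped with a warning (only traits with phenotypes for more than half
#' the cultivars are analysable by default).
#'
#' @param path CSV path.
#' @param h2 optional named per-trait heritabilities to attach.
#' @param min_phenotyped minimum fraction of non-missing phenotypes
#'   (default 0.5, exclusive: a trait at exactly 50\% coverage is kept).
#' @return A `phenotype_table` list: `pheno` data.frame and `h2`.
#' @export
read_phenotypes <- function(path, h2 = NULL, min_phenotyped = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop_invalid("CSV must have a sample_id column")
  if (anyDuplicated(df$sample_id)) {
    stop_invalid(sprintf("duplicate sample ids: %s",
                         paste(unique(df$sample_id[duplicated(df$sample_id)]),
                               collapse = ", ")))
  }
  traits <- setdiff(names(df), "sample_id")
  if (!length(traits)) stop_invalid("no trait columns found")
  for (tr in traits) {
    col <- df[[tr]]
    if (is.character(col)) {
      col[col == ""] <- NA
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(parsed))
      if (length(bad)) {
        stop_invalid(sprintf("non-numeric value in column '%s', row %d: '%s'",
                             tr, bad[1], col[bad[1]]))
      }
      df[[tr]] <- parsed
    }
  }
  coverage <- vapply(traits, function(tr) mean(!is.na(df[[tr]])), numeric(1))
  drop <- traits[coverage < min_phenotyped]
  if (length(drop)) {
    warning(sprintf("dropping trait(s) with < %.0f%% phenotyped samples: %s",
                    100 * min_phenotyped, paste(drop, collapse = ", ")))
    df <- df[, c("sample_id", setdiff(traits, drop)), drop = FALSE]
    traits <- setdiff(traits, drop)
  }
  if (!is.null(h2)) h2 <- h2[intersect(names(h2), traits)]
  structure(list(pheno = df, h2 = h2), class = "phenotype_table")
}

#' Write a phenotype table as CSV
#' @param pt a `phenotype_table` (or plain data.frame with `sample_id`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(pt, path) {
  df <- if (inherits(pt, "phenotype_table")) pt$pheno else pt
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the simulation truth sidecar (JSON)
#'
#' Stores the per-locus true effects, heritability target and seed alongside
#' simulated VCF/CSV outputs so downstream accuracy can be scored against
#' truth.
#'
#' @param truth a `sim_truth`.
#' @param path JSON path.
#' @return `read_truth_json` returns the parsed list.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(h2_target = truth$h2_target, seed = truth$seed,
         loci = truth$loci, true_effects = truth$true_effects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
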