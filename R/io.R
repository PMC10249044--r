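# Readers/writers for the package's plain-text interchange formats:
# dosage CSV (rows = individuals, columns = loci, NA = missing), minimal
# VCF 4.2 (GT only, biallelic), GRM long CSV, nest-record CSV, and flat
# key=value config files.

#' Write / read a dosage CSV
#'
#' Rows are individuals (first column `id`), remaining columns are loci
#' with values 0/1/2 and `NA` for missing.
#'
#' @param g a [genotypes] object; `path` file path.
#' @name genotype_csv
#' @export
write_genotypes_csv <- function(g, path) {
  stopifnot(inherits(g, "genotypes"))
  df <- data.frame(id = rownames(g$dosage), g$dosage, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname genotype_csv
#' @param path file path.
#' @param meta optional metadata tibble passed to [genotypes()].
#' @export
read_genotypes_csv <- function(path, meta = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  genotypes(m, meta)
}

#' Write / read a minimal VCF 4.2 (GT field only)
#'
#' Biallelic sites only; dosage 0/1/2 maps to `0/0`, `0/1`, `1/1` and
#' missing to `./.`. Reading goes through `vcfR` and rejects multiallelic
#' records with a clear error.
#'
#' @param g a [genotypes] object; `path` file path.
#' @name genotype_vcf
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotypes"))
  ids <- rownames(g$dosage)
  loci <- colnames(g$dosage)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_along(loci), function(k) {
    d <- g$dosage[, k]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c("1", k, loci[k], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname genotype_vcf
#' @param path file path.
#' @param meta optional metadata tibble passed to [genotypes()].
#' @export
read_genotypes_vcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    abort("multiallelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  to_dosage <- function(x) {
    x <- gsub("\\|", "/", x)
    unname(c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)[x])
  }
  d <- apply(gt, 2, to_dosage)
  rownames(d) <- rownames(gt)
  genotypes(t(d), meta)
}

#' Write a relatedness matrix as long-format CSV
#'
#' Columns `id1,id2,relatedness,n_loci`, one row per unordered pair.
#'
#' @param grm a `grm` object; `path` file path.
#' @export
write_grm_csv <- function(grm, path) {
  write.csv(as.data.frame(grm_tidy(grm)), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read nest records CSV
#'
#' @param records nest tibble; `path` file path.
#' @name nest_csv
#' @export
write_nest_records_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname nest_csv
#' @param path file path.
#' @export
read_nest_records_csv <- function(path) {
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  for (col in intersect(c("mother_id", "father_id"), names(x)))
    x[[col]][x[[col]] == ""] <- NA_character_
  x
}

#' Write / read a flat key=value configuration file
#'
#' @param config a [sim_config()] (or any flat named list); `path` file
#'   path.
#' @name config_io
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' @rdname config_io
#' @param path file path.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Write an EPP summary as JSON
#'
#' One cell per species x cavity type with brood- and offspring-level
#' counts and integer percentages, mirroring the package's summary
#' table.
#'
#' @param summary an `epp_summary` from [summarize_epp()]; `path` file
#'   path.
#' @export
write_epp_summary_json <- function(summary, path) {
  cells <- purrr::pmap(as.list(summary), function(...) {
    row <- list(...)
    list(
      broods = list(extra_pair = row$n_epp_broods,
                    within_pair = row$n_broods - row$n_epp_broods,
                    pct_extra_pair = row$brood_pct),
      offspring = list(extra_pair = row$n_epo,
                       within_pair = row$n_offspring - row$n_epo,
                       pct_extra_pair = row$offspring_pct)
    )
  })
  names(cells) <- paste(summary$species, summary$cavity_type, sep = ".")
  jsonlite::write_json(cells, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write parentage calls as CSV files
#'
#' Emits pair-level (`father_offspring.csv`, `sibling_pairs.csv`,
#' `epf_links.csv`) and offspring-level (`offspring.csv`) tables plus
#' the per-nest table (`nests.csv`) into a directory.
#'
#' @param calls a `parentage_calls` object from [call_parentage()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_parentage_csv <- function(calls, dir) {
  stopifnot(inherits(calls, "parentage_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("father_offspring", "sibling_pairs", "epf_links",
               "offspring", "nests"))
    write.csv(as.data.frame(calls[[nm]]),
              file.path(dir, paste0(nm, ".csv")), row.names = FALSE, na = "")
  invisible(dir)
}
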