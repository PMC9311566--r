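#' Write genotypes as a minimal VCF
#'
#' One sample column per animal, GT field only, alleles A/B. Positions are
#' 1-based as stored.
#'
#' @param genotypes a [geno_matrix()].
#' @param path output file (plain text, `.vcf`).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  calls <- genotypes$calls
  map <- genotypes$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=crossherd",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(calls)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(map$chrom[j], map$pos[j],
                       paste0("v", map$chrom[j], "_", map$pos[j]),
                       "A", "B", ".", "PASS",
                       paste0("CLASS=", map$class[j]), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Requires the `vcfR` package; alternate-allele dosages are extracted
#' from the GT strings.
#'
#' @param path VCF file.
#' @return a [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, 2, function(col) {
    ifelse(is.na(col) | col %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", col), "/"),
                  function(al) sum(as.integer(al)), integer(1)))
  })
  calls <- t(dose)
  storage.mode(calls) <- "integer"
  fix <- vcfR::getFIX(v)
  cls <- sub("^CLASS=", "", sub(";.*$", "", v@fix[, "INFO"]))
  map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    class = cls, stringsAsFactors = FALSE)
  geno_matrix(calls, map)
}

#' Write/read the tab-separated genotype dialect
#'
#' Rows are animals, columns are variants named `chrom_pos`, codes
#' 0/1/2/NA.
#'
#' @param genotypes a [geno_matrix()].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- as.data.frame(genotypes$calls)
  names(df) <- variant_names(genotypes)
  df <- cbind(id = rownames(genotypes$calls), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param class_col annotation class assigned to all variants on read.
#' @export
read_genotypes_tsv <- function(path, class_col = "unknown") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$id
  calls <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- ids
  parts <- strsplit(colnames(calls), "_")
  map <- data.frame(chrom = as.integer(vapply(parts, `[`, "", 1)),
                    pos = as.integer(vapply(parts, `[`, "", 2)),
                    class = class_col, stringsAsFactors = FALSE)
  geno_matrix(calls, map)
}

#' Write/read a pedigree with breed compositions as CSV
#'
#' Composition columns are prefixed `comp_`.
#'
#' @param pedigree a `herd_pedigree`.
#' @param path output file.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  comp <- breed_composition(pedigree)
  df <- cbind(as.data.frame(pedigree),
              stats::setNames(as.data.frame(comp),
                              paste0("comp_", colnames(comp))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cc <- grep("^comp_", names(df))
  comp <- as.matrix(df[, cc, drop = FALSE])
  colnames(comp) <- sub("^comp_", "", colnames(comp))
  rownames(comp) <- df$id
  df$sire[df$sire == ""] <- NA
  df$dam[df$dam == ""] <- NA
  herd_pedigree(df[, -cc, drop = FALSE], comp)
}

#' Write/read the event log as CSV
#' @param events a `herd_events` or event data.frame.
#' @param path output file.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(event_frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Round-trip true simulation parameters through YAML
#' @param params a [true_params()].
#' @param path output file.
#' @export
write_params_yaml <- function(params, path) {
  pl <- unclass(params)
  pl$K_a <- as.numeric(pl$K_a)
  pl$K_d <- as.numeric(pl$K_d)
  if (!is.null(pl$K_pe)) pl$K_pe <- as.numeric(pl$K_pe)
  yaml::write_yaml(pl, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  pl <- yaml::read_yaml(path)
  kdim <- pl$order + 1
  mk <- function(v) if (is.null(v)) NULL else matrix(v, kdim, kdim)
  true_params(K_a = mk(pl$K_a), K_d = mk(pl$K_d), K_pe = mk(pl$K_pe),
              sigma2_e = pl$sigma2_e, dom_mean = pl$dom_mean,
              conception_base = pl$conception_base,
              conception_het = pl$conception_het, order = pl$order,
              age_range = unlist(pl$age_range), max_age = pl$max_age,
              cw_base = pl$cw_base, cw_gain = pl$cw_gain,
              calf_base = pl$calf_base,
              calf_sex_effect = pl$calf_sex_effect,
              calf_sd = pl$calf_sd, wean_prob = pl$wean_prob,
              miss_cw = pl$miss_cw, causal_frac = pl$causal_frac,
              var_a = pl$var_a, var_d = pl$var_d)
}
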