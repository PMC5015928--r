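# Readers and writers for the HapMap-style genotype TSV dialect, VCF,
# the sample-panel CSV, and square IBS matrix export.

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read a genotype table
#'
#' Reads a HapMap-style tab-separated genotype table (header
#' `rs chrom pos alleles` followed by one column per line; calls as
#' two-letter diplotypes such as `AA`/`AG`/`NN` or single-letter IUPAC
#' codes) or a VCF 4.x file. Sites with more than two observed alleles are
#' dropped with a warning; markers are sorted by position within
#' chromosome (with a warning if the input was unsorted) and given 1-based
#' per-chromosome indices.
#'
#' @param path Path to the file.
#' @param format `"hapmap_tsv"` or `"vcf"`.
#' @param panel Optional sample panel to attach (see
#'   [assign_cohorts_and_populations()]).
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, format = c("hapmap_tsv", "vcf"),
                                panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_genotype_table: no such file: ", path)
  g <- switch(format,
              hapmap_tsv = .read_hapmap(path),
              vcf = .read_vcf(path))
  ord <- order(g$map$chrom, g$map$pos)
  if (!identical(ord, seq_len(nrow(g$map)))) {
    warning("read_genotype_table: markers were not position-sorted; sorting")
    g$map <- g$map[ord, , drop = FALSE]
    g$calls <- g$calls[, ord, drop = FALSE]
  }
  g$map$index <- as.integer(stats::ave(g$map$pos, g$map$chrom, FUN = seq_along))
  rownames(g$map) <- NULL
  genotype_matrix(g$calls, g$map, panel = panel)
}

.decode_call <- function(x, a0, a1) {
  # returns integer call code given allele letters a0/a1 for the site
  x <- toupper(x)
  n <- nchar(x)
  out <- rep(NA_integer_, length(x))
  miss <- x %in% c("N", "NN", "--", "-", "./.", ".")
  one <- n == 1L & !miss
  homo1 <- one & x == a0; homo2 <- one & x == a1
  hetc <- one & x %in% names(IUPAC_HET)
  out[homo1] <- CALL_A0; out[homo2] <- CALL_A1; out[hetc] <- CALL_HET
  two <- n == 2L & !miss
  f <- substr(x, 1, 1); s <- substr(x, 2, 2)
  out[two & f == a0 & s == a0] <- CALL_A0
  out[two & f == a1 & s == a1] <- CALL_A1
  out[two & f != s & (f %in% c(a0, a1)) & (s %in% c(a0, a1))] <- CALL_HET
  bad <- !miss & is.na(out)
  attr(out, "n_bad") <- sum(bad)
  out
}

.read_hapmap <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_genotype_table: empty file (line 1)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 ||
      !identical(tolower(header[1:4]), c("rs", "chrom", "pos", "alleles")))
    stop("read_genotype_table: malformed header at line 1 ",
         "(expected 'rs\\tchrom\\tpos\\talleles\\t<lines...>')")
  line_ids <- header[-(1:4)]
  nfield <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != nfield))
    stop("read_genotype_table: malformed row at line ",
         which(lens != nfield)[1] + 1L, " (expected ", nfield, " fields, got ",
         lens[lens != nfield][1], ")")
  tab <- do.call(rbind, rows)
  alleles <- strsplit(tab[, 4], "/", fixed = TRUE)
  multi <- lengths(alleles) != 2L
  calls <- matrix(NA_integer_, length(line_ids), nrow(tab))
  bad_site <- multi
  for (j in which(!multi)) {
    dec <- .decode_call(tab[j, -(1:4)], alleles[[j]][1], alleles[[j]][2])
    if (attr(dec, "n_bad") > 0) bad_site[j] <- TRUE else calls[, j] <- dec
  }
  if (any(bad_site))
    warning("read_genotype_table: dropped ", sum(bad_site),
            " site(s) with >2 alleles or calls outside the stated alleles")
  keep <- !bad_site
  a0 <- vapply(alleles[keep], `[`, "", 1)
  a1 <- vapply(alleles[keep], `[`, "", 2)
  pos <- suppressWarnings(as.integer(tab[keep, 3]))
  if (anyNA(pos))
    stop("read_genotype_table: non-numeric position at line ",
         which(keep)[which(is.na(pos))[1]] + 1L)
  map <- data.frame(marker = tab[keep, 1], chrom = tab[keep, 2], pos = pos,
                    index = NA_integer_, allele0 = a0, allele1 = a1,
                    stringsAsFactors = FALSE)
  calls <- calls[, keep, drop = FALSE]
  dimnames(calls) <- list(line_ids, map$marker)
  list(calls = calls, map = map)
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotype_table: the vcfR package is required for format='vcf'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE) | is.na(alt) | alt == "."
  if (any(multi))
    warning("read_genotype_table: dropped ", sum(multi),
            " multi-allelic or ALT-less VCF record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- sub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0")] <- CALL_A0
  code[gt %in% c("1/1", "1")] <- CALL_A1
  code[gt %in% c("0/1", "1/0")] <- CALL_HET
  keep <- !multi
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste(fix[no_id, "CHROM"], fix[no_id, "POS"], sep = "_")
  map <- data.frame(marker = id[keep], chrom = fix[keep, "CHROM"],
                    pos = as.integer(fix[keep, "POS"]), index = NA_integer_,
                    allele0 = fix[keep, "REF"], allele1 = alt[keep],
                    stringsAsFactors = FALSE)
  calls <- t(code[keep, , drop = FALSE])
  dimnames(calls) <- list(colnames(gt), map$marker)
  list(calls = calls, map = map)
}

#' Write a genotype table in the HapMap-style TSV dialect
#'
#' Emits the same dialect [read_genotype_table()] reads: header
#' `rs chrom pos alleles` plus one column per line, calls as two-letter
#' diplotypes (`NN` for missing).
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  map <- g$map
  n_mark <- nrow(map)
  enc <- matrix("NN", nrow(g$calls), n_mark)
  for (code in list(c(CALL_A0, "allele0", "allele0"),
                    c(CALL_A1, "allele1", "allele1"),
                    c(CALL_HET, "allele0", "allele1"))) {
    hit <- which(g$calls == as.integer(code[1]))
    if (length(hit)) {
      jj <- (hit - 1L) %/% nrow(g$calls) + 1L
      enc[hit] <- paste0(map[[code[2]]][jj], map[[code[3]]][jj])
    }
  }
  out <- cbind(map$marker, map$chrom, map$pos,
               paste(map$allele0, map$allele1, sep = "/"), t(enc))
  colnames(out) <- c("rs", "chrom", "pos", "alleles", rownames(g$calls))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample panel CSV
#'
#' Expects columns `line_id,maturity_group,year_of_release`; cohort and
#' population assignments are added via
#' [assign_cohorts_and_populations()].
#'
#' @param path CSV path.
#' @return Panel `data.frame` with `cohort` and `population` columns.
#' @export
read_panel_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(line_id = "character",
                                          maturity_group = "character"))
  need <- c("line_id", "maturity_group", "year_of_release")
  if (!all(need %in% names(panel)))
    stop("read_panel_csv: required columns: ", paste(need, collapse = ", "))
  assign_cohorts_and_populations(panel)
}

#' Write an IBS matrix as a square TSV
#'
#' @param ibs An `ibs_matrix` from [ibs_matrix()].
#' @param path Output path.
#' @param header Optional `#`-prefixed metadata lines to prepend.
#' @return `path`, invisibly.
#' @export
write_ibs_tsv <- function(ibs, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("line_id", colnames(ibs$values)), collapse = "\t"), con)
  utils::write.table(ibs$values, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}
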