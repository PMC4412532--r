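## Direct-to-consumer (DTC) raw genotype dialect:
##   '#'-prefixed comment lines, then data lines
##   rsid<TAB>chromosome<TAB>position<TAB>genotype
## genotype is two bases (unphased, unordered), one base (hemizygous),
## "--" (no call), or insertion/deletion codes ("II", "DD", "DI").

genotype_token_re <- "^([ACGTID]{1,2}|--)$"

#' Construct a genotype profile
#'
#' A genotype profile holds one individual's unphased genotype calls keyed
#' by rsID, as parsed from a DTC raw data file. Two-base genotypes are
#' unordered: `"AG"` and `"GA"` are the same call and are stored with
#' alleles in lexicographic order.
#'
#' @param individual_id Identifier string.
#' @param calls Data frame with columns `rsid`, `chrom`, `position`,
#'   `genotype`.
#' @param build Genome-build label; carried as an opaque string and checked
#'   against the panel's label at assessment time.
#' @return An object of class `genotype_profile`.
#' @export
genotype_profile <- function(individual_id, calls, build = "GRCh37") {
  stopifnot(is.data.frame(calls),
            all(c("rsid", "chrom", "position", "genotype") %in% names(calls)))
  calls <- calls[, c("rsid", "chrom", "position", "genotype")]
  calls$rsid <- as.character(calls$rsid)
  calls$chrom <- as.character(calls$chrom)
  calls$position <- as.integer(calls$position)
  calls$genotype <- normalize_genotype(as.character(calls$genotype))
  if (anyDuplicated(calls$rsid)) {
    stop("duplicate rsid in profile calls", call. = FALSE)
  }
  rownames(calls) <- NULL
  structure(list(individual_id = individual_id, build = build, calls = calls),
            class = "genotype_profile")
}

## Sort the two alleles of a diploid call so unordered pairs compare equal.
normalize_genotype <- function(g) {
  bad <- !grepl(genotype_token_re, g)
  if (any(bad)) {
    stop("invalid genotype token: ", g[which(bad)[1]], call. = FALSE)
  }
  two <- nchar(g) == 2 & g != "--"
  a1 <- substr(g[two], 1, 1)
  a2 <- substr(g[two], 2, 2)
  swap <- a2 < a1
  g[two][swap] <- paste0(a2[swap], a1[swap])
  g
}

#' Parse a direct-to-consumer raw genotype file
#'
#' Reads the 4-column tab-separated DTC dialect. Comment lines beginning
#' `#` are skipped (an `# individual_id:` / `# build:` comment, if present,
#' supplies defaults for the corresponding arguments). Two-base genotype
#' strings become unordered allele pairs, single bases hemizygous calls,
#' `"--"` a missing call; `I`/`D` codes parse but are excluded as non-SNP
#' at panel-matching time.
#'
#' A malformed data line (wrong column count or invalid genotype token) is
#' an error naming the line number. A duplicated rsID keeps the first call
#' and raises a warning, so no data line is ever silently dropped.
#'
#' @param path Path to a raw genotype file.
#' @param individual_id Identifier; defaults to an `# individual_id:`
#'   comment or, failing that, the file name.
#' @param build Build label; defaults to a `# build:` comment or "unknown".
#' @return A [genotype_profile()].
#' @export
parse_raw_genotypes <- function(path, individual_id = NULL, build = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (is.null(individual_id)) {
    m <- grep("^#\\s*individual_id\\s*:", lines, value = TRUE)
    individual_id <- if (length(m)) {
      trimws(sub("^#\\s*individual_id\\s*:", "", m[1]))
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  if (is.null(build)) {
    m <- grep("^#\\s*build\\s*:", lines, value = TRUE)
    build <- if (length(m)) trimws(sub("^#\\s*build\\s*:", "", m[1])) else "unknown"
  }
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  data_lineno <- which(is_data)
  dl <- lines[is_data]
  if (length(dl) == 0) {
    return(genotype_profile(individual_id,
                            data.frame(rsid = character(), chrom = character(),
                                       position = integer(),
                                       genotype = character()),
                            build = build))
  }
  parts <- strsplit(dl, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4)) {
    i <- which(nf != 4)[1]
    stop(sprintf("malformed line %d: expected 4 tab-separated fields, found %d",
                 data_lineno[i], nf[i]), call. = FALSE)
  }
  mat <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  geno <- mat[, 4]
  bad <- !grepl(genotype_token_re, geno)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed line %d: invalid genotype '%s'",
                 data_lineno[i], geno[i]), call. = FALSE)
  }
  calls <- data.frame(rsid = mat[, 1], chrom = mat[, 2],
                      position = suppressWarnings(as.integer(mat[, 3])),
                      genotype = geno, stringsAsFactors = FALSE)
  dup <- duplicated(calls$rsid)
  if (any(dup)) {
    warning("duplicate rsid(s) in ", basename(path), ", keeping first call: ",
            paste(unique(calls$rsid[dup]), collapse = ", "), call. = FALSE)
    calls <- calls[!dup, , drop = FALSE]
  }
  genotype_profile(individual_id, calls, build = build)
}

#' Write a genotype profile as a DTC-dialect raw file
#'
#' The emitted file round-trips through [parse_raw_genotypes()] to an
#' equal profile; diploid genotypes are serialized with alleles in
#' lexicographic order.
#'
#' @param profile A `genotype_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_genotypes <- function(profile, path) {
  stopifnot(inherits(profile, "genotype_profile"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# individual_id: %s", profile$individual_id),
               sprintf("# build: %s", profile$build),
               "# rsid\tchromosome\tposition\tgenotype"), con)
  calls <- profile$calls
  if (nrow(calls) > 0) {
    writeLines(paste(calls$rsid, calls$chrom, calls$position, calls$genotype,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("<genotype_profile> %s: %d calls, build %s\n",
              x$individual_id, nrow(x$calls), x$build))
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.genotype_profile <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}
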