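# Readers/writers for GeneNetwork-style genotype files, trait matrices and
# covariates, plus strain alignment across inputs.

#' Default allele-code-to-dosage map
#'
#' Maps the GeneNetwork allele codes of a two-founder population to dosages:
#' `B` (first founder) to 0, `D` (second founder) to 1, `H` (heterozygous) to
#' 0.5, and `U` (unknown) to missing (`NA`).
#'
#' @return Named numeric vector mapping allele codes to dosages.
#' @export
default_code_map <- function() {
  c(B = 0, D = 1, H = 0.5, U = NA_real_)
}

#' Read a GeneNetwork-style `.geno` genotype file
#'
#' The dialect: lines starting with `@` (metadata) or `#` (comments) are
#' skipped; the first remaining line is a header beginning with the columns
#' `Chr`, `Locus`, `cM` and optionally `Mb`, followed by strain names; each
#' subsequent line holds one marker with its map position and one allele code
#' per strain. Fields are tab- or whitespace-delimited.
#'
#' @param path Path to the `.geno` file.
#' @param code_map Named numeric vector mapping allele codes to dosages
#'   (`NA` marks a code as missing). Default [default_code_map()].
#' @param sep Field separator passed to [strsplit()]; the default `"[ \t]+"`
#'   splits on runs of tabs or spaces.
#' @return A `genotype_matrix`: list with `dosage` (strains x markers numeric
#'   matrix, dimnames set), `strain_ids`, and `map` (data.frame with columns
#'   `marker`, `chr`, `cM` and, when present in the file, `Mb`).
#' @export
read_geno <- function(path, code_map = default_code_map(), sep = "[ \t]+") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(@|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("no header/data lines in ", path)

  split1 <- function(x) strsplit(trimws(x), sep)[[1L]]
  header <- split1(lines[1L])
  if (length(header) < 4L || tolower(header[1L]) != "chr" ||
      tolower(header[2L]) != "locus" || tolower(header[3L]) != "cm") {
    stop("header must start with columns Chr, Locus, cM: got '",
         paste(utils::head(header, 4L), collapse = " "), "'")
  }
  has_mb <- length(header) >= 4L && tolower(header[4L]) == "mb"
  n_meta <- if (has_mb) 4L else 3L
  strain_ids <- header[-seq_len(n_meta)]
  if (length(strain_ids) < 1L) stop("no strain columns in header")
  if (anyDuplicated(strain_ids))
    stop("duplicate strain ids in header: ",
         paste(unique(strain_ids[duplicated(strain_ids)]), collapse = ", "))

  rows <- lapply(lines[-1L], split1)
  nf <- lengths(rows)
  want <- n_meta + length(strain_ids)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop("ragged row at line ", lineno[-1L][bad], ": expected ", want,
         " fields, got ", nf[bad])
  }
  meta <- do.call(rbind, lapply(rows, function(r) r[seq_len(n_meta)]))
  marker <- meta[, 2L]
  if (anyDuplicated(marker))
    stop("duplicate marker id: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))

  codes <- do.call(rbind, lapply(rows, function(r) r[-seq_len(n_meta)]))
  unknown <- setdiff(unique(as.vector(codes)), names(code_map))
  if (length(unknown)) {
    hit <- which(matrix(codes %in% unknown, nrow(codes)), arr.ind = TRUE)[1L, ]
    stop("unknown allele code '", codes[hit[1L], hit[2L]], "' at line ",
         lineno[-1L][hit[1L]], " (marker ", marker[hit[1L]], ")")
  }
  # codes matrix is markers x strains; store strains x markers
  dosage <- matrix(code_map[codes], nrow = nrow(codes), ncol = ncol(codes))
  dosage <- t(dosage)
  dimnames(dosage) <- list(strain_ids, marker)

  map <- data.frame(marker = marker, chr = meta[, 1L],
                    cM = as.numeric(meta[, 3L]),
                    stringsAsFactors = FALSE)
  if (has_mb) map$Mb <- suppressWarnings(as.numeric(meta[, 4L]))
  new_genotype_matrix(dosage, map)
}

#' Construct a genotype matrix object
#'
#' @param dosage Numeric matrix, strains x markers, entries in `[0, 1]` or
#'   `NA`; dimnames give strain and marker ids.
#' @param map data.frame with columns `marker`, `chr`, `cM` (optionally `Mb`)
#'   matching the columns of `dosage`.
#' @return A `genotype_matrix` object.
#' @export
new_genotype_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), is.data.frame(map),
            all(c("marker", "chr", "cM") %in% names(map)),
            ncol(dosage) == nrow(map))
  if (anyDuplicated(map$marker)) stop("duplicate marker ids in map")
  if (is.null(rownames(dosage))) stop("dosage must have strain row names")
  if (anyDuplicated(rownames(dosage))) stop("duplicate strain ids")
  colnames(dosage) <- map$marker
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("dosages must lie in [0, 1]")
  structure(list(dosage = dosage, strain_ids = rownames(dosage), map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " strains x ", ncol(x$dosage),
      " markers on ", length(unique(x$map$chr)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read a trait (expression) matrix from delimited text
#'
#' Expects a header row of trait ids and a first column of strain ids; the
#' remaining cells are numeric with a configurable missing token.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; default `"\t"` unless the path ends in
#'   `.csv`, in which case `","`.
#' @param missing_token String marking a missing value (default `"NA"`).
#' @return A `trait_matrix`: list with `values` (strains x traits numeric
#'   matrix), `strain_ids`, `trait_ids`, and `annotation` (`NULL`; see
#'   [set_trait_annotation()]).
#' @export
read_traits <- function(path, sep = NULL, missing_token = "NA") {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2L) stop("trait file needs a strain column plus >=1 trait")
  strain_ids <- raw[[1L]]
  trait_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals == missing_token] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell '", vals[bad[1L, 1L], bad[1L, 2L]], "' at row ",
         bad[1L, 1L], " (strain ", strain_ids[bad[1L, 1L]], "), trait ",
         trait_ids[bad[1L, 2L]])
  }
  dimnames(num) <- list(strain_ids, trait_ids)
  message("read_traits: ", nrow(num), " strains x ", ncol(num), " traits")
  new_trait_matrix(num)
}

#' Construct a trait matrix object
#'
#' @param values Numeric matrix, strains x traits, dimnames set.
#' @param annotation Optional data.frame of cognate-gene positions with
#'   columns `trait`, `chr`, `pos` (Mb or cM on the plotting axis).
#' @return A `trait_matrix` object.
#' @export
new_trait_matrix <- function(values, annotation = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("trait values must carry strain row names and trait column names")
  if (anyDuplicated(colnames(values))) stop("duplicate trait ids")
  if (anyDuplicated(rownames(values))) stop("duplicate strain ids")
  structure(list(values = values, strain_ids = rownames(values),
                 trait_ids = colnames(values), annotation = annotation),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("<trait_matrix> ", nrow(x$values), " strains x ", ncol(x$values),
      " traits\n", sep = "")
  invisible(x)
}

#' Attach cognate-gene positions to a trait matrix
#'
#' @param traits A `trait_matrix`.
#' @param annotation data.frame with columns `trait`, `chr`, `pos`.
#' @return The trait matrix with `annotation` set.
#' @export
set_trait_annotation <- function(traits, annotation) {
  stopifnot(inherits(traits, "trait_matrix"),
            all(c("trait", "chr", "pos") %in% names(annotation)))
  traits$annotation <- annotation
  traits
}

#' Read a covariate matrix from delimited text
#'
#' Same layout as [read_traits()] (strain ids in column 1, covariates in the
#' remaining columns). An intercept column of ones is prepended unless the
#' first covariate column is already constant 1.
#'
#' @inheritParams read_traits
#' @return A `covariate_matrix`: numeric matrix (strains x covariates) with a
#'   leading intercept column, carrying strain row names.
#' @export
read_covariates <- function(path, sep = NULL, missing_token = "NA") {
  tm <- suppressMessages(read_traits(path, sep = sep, missing_token = missing_token))
  if (anyNA(tm$values)) stop("covariates may not contain missing values")
  new_covariate_matrix(tm$values)
}

#' Construct a covariate matrix (intercept enforced)
#'
#' @param values Numeric matrix of covariates, strains x c, strain row names
#'   set. An intercept column is prepended if the first column is not already
#'   all ones.
#' @return A `covariate_matrix` object (numeric matrix subclass).
#' @export
new_covariate_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("covariates must carry strain row names")
  if (ncol(values) == 0L || !all(values[, 1L] == 1)) {
    values <- cbind(intercept = 1, values)
  } else {
    colnames(values)[1L] <- "intercept"
  }
  qrZ <- qr(values)
  if (qrZ$rank < ncol(values)) {
    dep <- setdiff(seq_len(ncol(values)), qrZ$pivot[seq_len(qrZ$rank)])
    stop("covariate matrix is rank deficient; dependent column(s): ",
         paste(colnames(values)[dep], collapse = ", "))
  }
  structure(values, class = c("covariate_matrix", class(values)))
}

#' Restrict genotype, trait and covariate inputs to shared strains
#'
#' Strains are intersected across the inputs and every output is reordered to
#' the genotype file's strain order (the canonical order), so downstream
#' matrix operations line up row-by-row.
#'
#' @param geno A `genotype_matrix`.
#' @param traits A `trait_matrix`.
#' @param covariates Optional `covariate_matrix`.
#' @return List with elements `geno`, `traits` and (if supplied)
#'   `covariates`, all restricted to the shared strains, plus `n` (number of
#'   shared strains).
#' @export
align_strains <- function(geno, traits, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(traits, "trait_matrix"))
  shared <- intersect(geno$strain_ids, traits$strain_ids)
  if (!is.null(covariates)) shared <- intersect(shared, rownames(covariates))
  if (length(shared) < 3L)
    stop("fewer than 3 shared strains across inputs (got ", length(shared), ")")
  # keep genotype-file order
  shared <- geno$strain_ids[geno$strain_ids %in% shared]
  g <- geno
  g$dosage <- g$dosage[shared, , drop = FALSE]
  g$strain_ids <- shared
  t2 <- traits
  t2$values <- t2$values[shared, , drop = FALSE]
  t2$strain_ids <- shared
  out <- list(geno = g, traits = t2, n = length(shared))
  if (!is.null(covariates)) {
    zv <- unclass(covariates)[shared, , drop = FALSE]
    out$covariates <- new_covariate_matrix(zv)
  }
  message("align_strains: n = ", length(shared), " shared strains")
  out
}

#' Drop incomplete columns (strict missing-data policy)
#'
#' Missing data are handled before scanning, not imputed: any trait with a
#' missing value across the aligned strains is removed. For genotype
#' matrices, markers with missing (e.g. `U`-coded) entries are removed the
#' same way.
#'
#' @param x A `trait_matrix` or `genotype_matrix`.
#' @return Object of the same class with incomplete columns removed.
#' @export
drop_incomplete <- function(x) UseMethod("drop_incomplete")

#' @export
drop_incomplete.trait_matrix <- function(x) {
  bad <- colSums(is.na(x$values)) > 0L
  if (all(bad)) stop("all traits have missing values; nothing left to scan")
  if (any(bad))
    message("drop_incomplete: removed ", sum(bad), " trait(s): ",
            paste(utils::head(x$trait_ids[bad], 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "")
  x$values <- x$values[, !bad, drop = FALSE]
  x$trait_ids <- colnames(x$values)
  if (!is.null(x$annotation))
    x$annotation <- x$annotation[x$annotation$trait %in% x$trait_ids, , drop = FALSE]
  x
}

#' @export
drop_incomplete.genotype_matrix <- function(x) {
  bad <- colSums(is.na(x$dosage)) > 0L
  if (all(bad)) stop("all markers have missing genotypes")
  if (any(bad))
    message("drop_incomplete: removed ", sum(bad), " marker(s) with missing genotypes")
  x$dosage <- x$dosage[, !bad, drop = FALSE]
  x$map <- x$map[!bad, , drop = FALSE]
  x
}

#' Write a `.geno` genotype file
#'
#' Inverse of [read_geno()] for complete two-class panels: dosages 0, 1 and
#' 0.5 are written as `B`, `D` and `H`; missing entries as `U`.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  code <- matrix("U", nrow(d), ncol(d))
  code[!is.na(d) & d == 0] <- "B"
  code[!is.na(d) & d == 1] <- "D"
  code[!is.na(d) & d == 0.5] <- "H"
  if (any(!is.na(d) & !(d %in% c(0, 0.5, 1))))
    stop("write_geno supports only dosages 0, 0.5, 1 or missing")
  has_mb <- "Mb" %in% names(geno$map)
  hdr <- c("Chr", "Locus", "cM", if (has_mb) "Mb", geno$strain_ids)
  body <- cbind(geno$map$chr, geno$map$marker,
                format(geno$map$cM, trim = TRUE),
                if (has_mb) format(geno$map$Mb, trim = TRUE), t(code))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@type:riset", con)
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a trait matrix as delimited text
#'
#' @param traits A `trait_matrix`.
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @param digits Significant digits for floats (default 6).
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path, digits = 6) {
  stopifnot(inherits(traits, "trait_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(strain = traits$strain_ids,
                   signif(traits$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-trait peak table as TSV
#'
#' Columns: `trait_id`, `marker_id`, `chromosome`, `position_cM`, `lod`.
#'
#' @param peaks Peak data.frame from a max-mode scan (see [scan_eqtl()]), or
#'   a `lod_result` in peaks mode.
#' @param path Output path.
#' @param digits Significant digits for floats (default 6).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, digits = 6) {
  if (inherits(peaks, "lod_result")) {
    if (is.null(peaks$peaks)) stop("lod_result is in full mode; use write_lod_matrix")
    peaks <- peaks$peaks
  }
  need <- c("trait_id", "marker_id", "chromosome", "position_cM", "lod")
  stopifnot(all(need %in% names(peaks)))
  out <- peaks[, need]
  out$position_cM <- signif(out$position_cM, digits)
  out$lod <- signif(out$lod, digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table written by [write_peaks()]
#'
#' @param path Path to a peak TSV.
#' @return data.frame with the peak columns.
#' @export
read_peaks <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Write a full LOD matrix as TSV (traits x markers)
#'
#' First column `trait_id`, then one column per marker, header row of marker
#' ids.
#'
#' @param lod A `lod_result` in full mode, or a traits x markers matrix with
#'   dimnames.
#' @param path Output path.
#' @param digits Significant digits for floats (default 6).
#' @return `path`, invisibly.
#' @export
write_lod_matrix <- function(lod, path, digits = 6) {
  if (inherits(lod, "lod_result")) {
    if (is.null(lod$lod)) stop("lod_result is in peaks mode; use write_peaks")
    lod <- lod$lod
  }
  stopifnot(is.matrix(lod), !is.null(rownames(lod)), !is.null(colnames(lod)))
  df <- data.frame(trait_id = rownames(lod), signif(lod, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a LOD matrix written by [write_lod_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, traits x markers, dimnames set.
#' @export
read_lod_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
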