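# Plain-text readers and writers. All user-facing marker indices are
# 1-based concatenated map indices; all tables are TSV/CSV with headers.

#' Read a marker map file
#'
#' Tab-separated with columns `chromosome`, `marker_id`, `position_cM`.
#' @param path File path.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "marker_id", "position_cM")
  if (!all(need %in% names(d)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  marker_map(chr = d$chromosome, pos = d$position_cM, marker = d$marker_id)
}

#' @rdname read_marker_map
#' @param map A [marker_map()] to write.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  utils::write.table(
    data.frame(chromosome = map$chr, marker_id = map$marker,
               position_cM = map$pos_cM),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a line-by-marker genotype file
#'
#' CSV with one row per line and one column per marker; values `1`/`-1`,
#' or the alias codes `A` (P1 homozygote, mapped to `+1`) and `B` (P2
#' homozygote, `-1`). Heterozygous or missing entries are rejected with
#' the offending row and column named.
#'
#' @param path File path.
#' @param map Optional [marker_map()]; if given, column count and names
#'   are checked against it.
#' @return Genotype matrix of `+1`/`-1` codes.
#' @export
read_genotypes <- function(path, map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("line_id" %in% names(d)) { rn <- d$line_id; d$line_id <- NULL } else rn <- NULL
  M <- as.matrix(d)
  conv <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  chr_codes <- c(A = 1, B = -1, `1` = 1, `-1` = -1)
  vals <- chr_codes[trimws(as.character(M))]
  conv[] <- vals
  if (anyNA(conv)) {
    bad <- which(is.na(conv), arr.ind = TRUE)[1, ]
    stop("unknown genotype code ", dQuote(trimws(as.character(M))[is.na(vals)][1]),
         " at line ", bad[1], ", marker column ",
         colnames(M)[bad[2]] %||% bad[2],
         " (expected 1/-1 or A/B homozygous codes)")
  }
  if (!is.null(map)) {
    if (ncol(conv) != nrow(map))
      stop("genotype file has ", ncol(conv), " markers but the map has ",
           nrow(map))
    colnames(conv) <- map$marker
  }
  if (!is.null(rn)) rownames(conv) <- rn
  storage.mode(conv) <- "integer"
  conv
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @rdname read_genotypes
#' @param genotypes Genotype matrix to write.
#' @export
write_genotypes <- function(genotypes, path) {
  G <- unclass(genotypes)
  d <- data.frame(line_id = seq_len(nrow(G)), G, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read transformation phenotypes
#'
#' CSV with `line_id` plus one column per transformation; family means,
#' when present, are written alongside as `L1 ... L4`.
#'
#' @param phen An `attc_phenotypes` object (or a data frame of Z columns).
#' @param path File path.
#' @param family_means Include family-mean columns.
#' @export
write_phenotypes <- function(phen, path, family_means = TRUE) {
  Z <- if (inherits(phen, "attc_phenotypes")) phen$Z else as.data.frame(phen)
  d <- data.frame(line_id = seq_len(nrow(Z)), Z)
  if (family_means && inherits(phen, "attc_phenotypes"))
    d <- cbind(d, phen$family_means)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"line_id" %in% names(d)) stop("phenotype file needs a line_id column")
  d
}

#' Write and read a scan result
#'
#' TSV mirroring the `attc_scan` columns plus the transformation id; a
#' map adds chromosome annotation for the marker indices.
#' @param scan An `attc_scan` data frame.
#' @param path File path.
#' @param map Optional [marker_map()] for chromosome columns.
#' @export
write_scan <- function(scan, path, map = NULL) {
  d <- as.data.frame(scan)
  d$transformation <- attr(scan, "transformation") %||% NA_character_
  if (!is.null(map)) {
    d$chr_k <- map$chr[d$k]
    d$chr_l <- map$chr[d$l]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  trans <- if ("transformation" %in% names(d) && nrow(d))
    d$transformation[1] else NA_character_
  d$transformation <- NULL
  structure(d, transformation = trans, class = c("attc_scan", "data.frame"))
}

#' Write a dissection result
#'
#' Two TSV tables side by side in one file would lose structure, so the
#' QTL and pair tables are written to `<path>` with a `table` column
#' distinguishing `qtl` and `pair` rows.
#' @param dissection An `attc_dissection` object.
#' @param path File path.
#' @export
write_dissection <- function(dissection, path) {
  q <- dissection$qtl; p <- dissection$pairs
  q$table <- rep("qtl", nrow(q)); p$table <- rep("pair", nrow(p))
  all_cols <- union(names(q), names(p))
  pad <- function(d) { d[setdiff(all_cols, names(d))] <- NA; d[all_cols] }
  utils::write.table(rbind(pad(q), pad(p)), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write study summaries
#' @param study An `attc_study` object.
#' @param dir Output directory; writes `augmented.csv`, `dissected.csv`
#'   and `lod_hits.csv`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$augmented, file.path(dir, "augmented.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dissected, file.path(dir, "dissected.csv"),
                   row.names = FALSE)
  utils::write.csv(study$n_lod_hits, file.path(dir, "lod_hits.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a key-value run configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' ignored; values are coerced to numeric when possible and comma-split
#' into vectors.
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}
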