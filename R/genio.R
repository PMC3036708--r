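#' Construct a genotype matrix object
#'
#' The central container of the package: a samples x loci matrix of diploid
#' allele dosages (copies of the A1 allele, 0/1/2, \code{NA} = missing) plus
#' per-locus map information.
#'
#' @param dosage integer matrix, samples x loci, values in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample identifiers.
#' @param locus_ids character vector of unique locus identifiers.
#' @param chrom per-locus chromosome label.
#' @param pos_bp per-locus 1-based base-pair position (non-negative integer);
#'   must be strictly increasing within each chromosome.
#' @param alleles loci x 2 character matrix giving (A1, A2) per locus.
#'
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, sample_ids, locus_ids, chrom, pos_bp,
                            alleles) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(sample_ids))
    stop("dosage has ", nrow(dosage), " rows but ", length(sample_ids),
         " sample ids")
  if (ncol(dosage) != length(locus_ids))
    stop("dosage has ", ncol(dosage), " columns but ", length(locus_ids),
         " locus ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (length(chrom) != length(locus_ids) || length(pos_bp) != length(locus_ids))
    stop("chrom/pos_bp length must equal number of loci")
  if (any(pos_bp < 0)) stop("pos_bp must be non-negative")
  for (ch in unique(chrom)) {
    p <- pos_bp[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("pos_bp not strictly increasing on chromosome ", ch)
  }
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(locus_ids) || ncol(alleles) != 2)
    stop("alleles must be a loci x 2 matrix")
  dimnames(dosage) <- list(sample_ids, locus_ids)
  structure(list(dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 locus_ids = as.character(locus_ids),
                 chrom = as.character(chrom),
                 pos_bp = as.integer(pos_bp),
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %s; missingness: %.3f%%\n",
              paste(unique(x$chrom), collapse = ","), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by sample and/or locus
#'
#' @param G a \code{genotype_matrix}.
#' @param samples sample ids or indices to keep (default all).
#' @param loci locus ids or indices to keep (default all).
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(G, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(G$sample_ids) else {
    if (is.character(samples)) match(samples, G$sample_ids) else samples
  }
  li <- if (is.null(loci)) seq_along(G$locus_ids) else {
    if (is.character(loci)) match(loci, G$locus_ids) else loci
  }
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(li)) stop("unknown locus id in subset")
  genotype_matrix(G$dosage[si, li, drop = FALSE],
                  G$sample_ids[si], G$locus_ids[li],
                  G$chrom[li], G$pos_bp[li],
                  G$alleles[li, , drop = FALSE])
}

#' Read PLINK PED/MAP text genotypes
#'
#' Parses the classic whitespace-delimited PED format (6 leading columns,
#' then two allele columns per locus) together with its MAP file.  Alleles
#' are recoded to dosage of A1, where A1 is the first non-missing allele
#' observed at the locus scanning samples in file order (within a genotype,
#' ties broken lexicographically).  "0 0" becomes missing.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chrom, id, genetic pos, bp pos).
#' @return A \code{genotype_matrix}.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  L <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("PED file has no samples")
  want <- 6L + 2L * L
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != want))
    stop("ragged PED row at line ", which(nf != want)[1], ": expected ",
         want, " fields, found ", nf[nf != want][1])
  ids <- vapply(toks, `[`, "", 2L)
  if (anyDuplicated(ids))
    stop("duplicate sample id in PED: ", ids[duplicated(ids)][1])
  # allele matrix: n x 2L
  am <- matrix(unlist(lapply(toks, `[`, 7:want)), nrow = n, byrow = TRUE)
  a_first <- am[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a_second <- am[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  a_first[a_first == "0"] <- NA
  a_second[a_second == "0"] <- NA
  if (any(xor(is.na(a_first), is.na(a_second))))
    stop("half-missing genotype (one allele '0') in PED")
  dosage <- matrix(NA_integer_, n, L)
  alleles <- matrix(NA_character_, L, 2)
  for (l in seq_len(L)) {
    x <- a_first[, l]; y <- a_second[, l]
    obs <- !is.na(x)
    u <- sort(unique(c(x[obs], y[obs])))
    if (length(u) > 2)
      stop("more than two alleles at locus ", map$id[l])
    if (length(u) == 0) {
      next  # all-missing locus: alleles unknown, dosage all NA
    }
    j <- which(obs)[1]
    a1 <- min(x[j], y[j])  # first genotype observed; lexicographic tie-break
    a2 <- setdiff(u, a1)
    alleles[l, ] <- c(a1, if (length(a2)) a2 else NA_character_)
    dosage[, l] <- (x == a1) + (y == a1)
  }
  genotype_matrix(dosage, ids, map$id, map$chrom, map$pos, alleles)
}

#' Write a genotype matrix as PLINK PED/MAP text files
#'
#' Missing genotypes are written as "0 0"; heterozygotes as "A1 A2".
#' Round-trips through \code{\link{read_ped_map}} reproduce the matrix.
#'
#' @param G a \code{genotype_matrix}.
#' @param out_prefix path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return Invisibly, a character vector of the two file paths.
#' @export
write_ped_map <- function(G, out_prefix) {
  n <- length(G$sample_ids); L <- length(G$locus_ids)
  if (n == 0L || L == 0L) stop("refusing to write an empty genotype matrix")
  a1 <- G$alleles[, 1]; a2 <- G$alleles[, 2]
  a1[is.na(a1)] <- "A"; a2[is.na(a2)] <- "B"  # placeholder for all-missing loci
  a2[is.na(G$alleles[, 2]) & !is.na(G$alleles[, 1])] <- "0"
  # a monomorphic locus has no observed A2; any written genotype is "a1 a1"
  a2[a2 == "0"] <- a1[a2 == "0"]
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  first <- matrix("0", n, L); second <- matrix("0", n, L)
  d <- G$dosage
  for (l in seq_len(L)) {
    dl <- d[, l]
    first[, l] <- ifelse(is.na(dl), "0", ifelse(dl >= 1, a1[l], a2[l]))
    second[, l] <- ifelse(is.na(dl), "0", ifelse(dl == 2, a1[l], a2[l]))
  }
  inter <- matrix("", n, 2L * L)
  inter[, seq(1, 2 * L, 2)] <- first
  inter[, seq(2, 2 * L, 2)] <- second
  lead <- cbind(G$sample_ids, G$sample_ids, "0", "0", "0", "-9")
  con <- try(file(ped_path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write ", ped_path)
  on.exit(close(con))
  writeLines(apply(cbind(lead, inter), 1, paste, collapse = " "), con)
  utils::write.table(data.frame(G$chrom, G$locus_ids, 0, G$pos_bp),
                     map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(c(ped = ped_path, map = map_path))
}

#' Read and validate a sample metadata table
#'
#' Expects a tab-separated file with header columns \code{sample_id},
#' \code{lat}, \code{lon}, \code{province}, \code{region}, \code{platform},
#' \code{status}.
#'
#' @param tsv_path path to the TSV file.
#' @return A validated \code{data.frame} (a "sample table").
#' @export
read_sample_metadata <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("metadata file not found: ", tsv_path)
  S <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "")
  need <- c("sample_id", "lat", "lon", "province", "region", "platform",
            "status")
  miss <- setdiff(need, names(S))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  lat <- suppressWarnings(as.numeric(S$lat))
  lon <- suppressWarnings(as.numeric(S$lon))
  bad <- which(is.na(lat) | is.na(lon))
  if (length(bad)) stop("unparseable coordinates at data row(s): ",
                        paste(bad, collapse = ", "))
  S$lat <- lat; S$lon <- lon
  validate_sample_table(S)
}

#' Validate a sample table
#'
#' @param S a data.frame with the sample-metadata columns.
#' @return \code{S}, with row names reset, if valid; otherwise an error.
#' @export
validate_sample_table <- function(S) {
  if (anyDuplicated(S$sample_id))
    stop("duplicate sample_id: ", S$sample_id[duplicated(S$sample_id)][1])
  if (any(S$lat < -90 | S$lat > 90))
    stop("latitude out of [-90, 90] for sample(s): ",
         paste(S$sample_id[S$lat < -90 | S$lat > 90], collapse = ", "))
  if (any(S$lon < -180 | S$lon > 180))
    stop("longitude out of [-180, 180] for sample(s): ",
         paste(S$sample_id[S$lon < -180 | S$lon > 180], collapse = ", "))
  if (!all(S$status %in% c("case", "control", "unknown")))
    stop("status must be one of case/control/unknown")
  pr <- unique(S[, c("province", "region")])
  if (anyDuplicated(pr$province))
    stop("province mapped to more than one region: ",
         pr$province[duplicated(pr$province)][1])
  rownames(S) <- NULL
  S
}

#' Align a genotype matrix with a sample table
#'
#' Samples present in only one of the two inputs are dropped with a warning
#' (partial metadata is common when merging datasets); the survivors are
#' returned in the genotype matrix's order.
#'
#' @param G a \code{genotype_matrix}.
#' @param S a sample table.
#' @return list with elements \code{G} and \code{S}, restricted to the
#'   common samples, in matching order.
#' @export
align_samples <- function(G, S) {
  common <- intersect(G$sample_ids, S$sample_id)
  if (length(common) == 0L) stop("no samples shared between genotypes and metadata")
  dropped <- setdiff(union(G$sample_ids, S$sample_id), common)
  if (length(dropped))
    warning(length(dropped), " sample(s) without both genotypes and metadata dropped")
  G2 <- subset_genotypes(G, samples = common)
  S2 <- S[match(common, S$sample_id), , drop = FALSE]
  rownames(S2) <- NULL
  list(G = G2, S = S2)
}
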