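#' @importFrom rlang .data
NULL

MISSING_GENO_CODE <- -9L

valid_bases <- c("A", "C", "G", "T")

#' Construct a reference panel object
#'
#' A reference panel anchors the ancestry space: N individuals with known
#' population labels, hard genotypes (alt-allele dosages 0/1/2, NA missing)
#' at L biallelic sites.
#'
#' @param genotypes N x L integer matrix over \{0, 1, 2, NA\}.
#' @param sites Tibble with columns site_id, chrom, pos, ref_allele,
#'   alt_allele; rows ordered by (chrom, pos), (chrom, pos) unique.
#' @param samples Tibble with columns sample_id, population and optionally
#'   region.
#' @param max_missing Maximum tolerated per-site missing fraction.
#' @return An object of class `ref_panel`.
#' @export
new_ref_panel <- function(genotypes, sites, samples, max_missing = 0.5) {
  genotypes <- as.matrix(genotypes)
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  if (!"region" %in% names(samples)) samples$region <- NA_character_
  validate_sites(sites)
  if (nrow(genotypes) != nrow(samples))
    stop(sprintf("genotype matrix has %d rows but sample table has %d",
                 nrow(genotypes), nrow(samples)))
  if (ncol(genotypes) != nrow(sites))
    stop(sprintf("genotype matrix has %d columns but site table has %d rows",
                 ncol(genotypes), nrow(sites)))
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("reference genotypes must be 0, 1, 2 or missing")
  if (anyNA(samples$population) || any(samples$population == ""))
    stop("every reference sample needs a population label")
  miss <- colMeans(is.na(genotypes))
  if (any(miss > max_missing))
    stop(sprintf("%d sites exceed the missing-fraction ceiling of %g",
                 sum(miss > max_missing), max_missing))
  structure(list(genotypes = genotypes, sites = sites, samples = samples),
            class = "ref_panel")
}

validate_sites <- function(sites) {
  need <- c("site_id", "chrom", "pos", "ref_allele", "alt_allele")
  if (!all(need %in% names(sites)))
    stop("site table must have columns ", paste(need, collapse = ", "))
  if (!all(sites$ref_allele %in% valid_bases) ||
      !all(sites$alt_allele %in% valid_bases))
    stop("site table contains a non-ACGT allele")
  if (any(sites$ref_allele == sites$alt_allele))
    stop("ref_allele must differ from alt_allele")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("(chrom, pos) must be unique in the site table")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("site table must be ordered by (chrom, pos)")
  invisible(sites)
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d samples x %d sites, %d populations\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$samples$population))))
  invisible(x)
}

#' Construct a study genotype set
#'
#' @param genotypes M x L' matrix over \{0,1,2,NA\}, columns aligned to
#'   `site_index`.
#' @param sample_ids Character vector of length M.
#' @param site_index Strictly increasing integer indices into the panel's
#'   site table.
#' @return An object of class `study_genotypes`.
#' @export
new_study_genotypes <- function(genotypes, sample_ids, site_index) {
  genotypes <- as.matrix(genotypes)
  site_index <- as.integer(site_index)
  if (length(site_index) != ncol(genotypes))
    stop("site_index length must match genotype columns")
  if (length(site_index) > 1 && any(diff(site_index) <= 0))
    stop("site_index must be strictly increasing")
  if (!all(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)))
    stop("study genotypes must be 0, 1, 2 or missing")
  structure(list(genotypes = genotypes, sample_ids = as.character(sample_ids),
                 site_index = site_index),
            class = "study_genotypes")
}

#' Construct a pileup matrix
#'
#' Sequence-mode input: per-sample, per-site total read depth, reference
#' allele read count, and a per-site base-error rate.
#'
#' @param depth,ref_count M x L' non-negative integer matrices.
#' @param error_rate Length-L' base-error probabilities in \[0, 0.5).
#' @param sample_ids Character vector of length M.
#' @param site_index Strictly increasing indices into the panel site table.
#' @return An object of class `pileup_matrix`.
#' @export
new_pileup_matrix <- function(depth, ref_count, error_rate, sample_ids,
                              site_index) {
  depth <- as.matrix(depth); ref_count <- as.matrix(ref_count)
  if (!identical(dim(depth), dim(ref_count)))
    stop("depth and ref_count dimensions differ")
  if (any(depth < 0) || any(ref_count < 0))
    stop("depth and ref_count must be non-negative")
  bad <- which(ref_count > depth, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("ref_count exceeds depth at sample row %d, site column %d",
                 bad[1, 1], bad[1, 2]))
  if (length(error_rate) != ncol(depth))
    stop("error_rate length must match site count")
  if (any(!is.finite(error_rate)) || any(error_rate < 0) ||
      any(error_rate >= 0.5))
    stop("error rates must be finite and in [0, 0.5)")
  site_index <- as.integer(site_index)
  if (length(site_index) > 1 && any(diff(site_index) <= 0))
    stop("site_index must be strictly increasing")
  structure(list(depth = depth, ref_count = ref_count,
                 error_rate = as.numeric(error_rate),
                 sample_ids = as.character(sample_ids),
                 site_index = site_index),
            class = "pileup_matrix")
}

#' Read a reference panel from its three-file on-disk form
#'
#' The dialect: `<prefix>.geno` holds one row per sample of
#' whitespace-separated integer dosages with -9 for missing; `<prefix>.site`
#' is a header + site_id/chrom/pos/ref/alt table; `<prefix>.sample` is a
#' header + sample_id/population\[/region\] table.
#'
#' @param prefix Path prefix; `.geno`, `.site` and `.sample` are appended.
#'   Alternatively pass the three paths explicitly.
#' @param geno_path,site_path,sample_path Explicit file paths (override the
#'   prefix).
#' @return A [ref_panel].
#' @export
read_reference_panel <- function(prefix = NULL, geno_path = NULL,
                                 site_path = NULL, sample_path = NULL) {
  if (!is.null(prefix)) {
    geno_path <- geno_path %||% paste0(prefix, ".geno")
    site_path <- site_path %||% paste0(prefix, ".site")
    sample_path <- sample_path %||% paste0(prefix, ".sample")
  }
  for (p in c(geno_path, site_path, sample_path))
    if (!file.exists(p)) stop("file not found: ", p)
  sites <- utils::read.table(site_path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "integer", "character",
                                            "character"))
  names(sites) <- c("site_id", "chrom", "pos", "ref_allele", "alt_allele")
  sites <- tibble::as_tibble(sites)
  samples <- utils::read.table(sample_path, header = TRUE, sep = "\t",
                               colClasses = "character")
  names(samples)[1:2] <- c("sample_id", "population")
  samples <- tibble::as_tibble(samples)
  lines <- readLines(geno_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- strsplit(trimws(lines), "[ \t]+")
  L <- nrow(sites)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != L)
      stop(sprintf("%s line %d has %d genotype columns; site file has %d rows",
                   geno_path, i, length(rows[[i]]), L))
  }
  G <- matrix(as.integer(unlist(rows)), nrow = length(rows), ncol = L,
              byrow = TRUE)
  G[G == MISSING_GENO_CODE] <- NA_integer_
  new_ref_panel(G, sites, samples)
}

#' Write a reference panel
#'
#' Inverse of [read_reference_panel()]; see that help page for the dialect.
#'
#' @param panel A [ref_panel].
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_reference_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "ref_panel"))
  G <- panel$genotypes
  G[is.na(G)] <- MISSING_GENO_CODE
  geno_path <- paste0(prefix, ".geno")
  writeLines(apply(G, 1, paste, collapse = " "), geno_path)
  site_path <- paste0(prefix, ".site")
  utils::write.table(panel$sites, site_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sample_path <- paste0(prefix, ".sample")
  utils::write.table(panel$samples, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(geno = geno_path, site = site_path, sample = sample_path))
}

#' Read study genotypes from a VCF, intersected with panel sites
#'
#' Records are matched to panel sites by (chrom, pos). When the VCF (REF, ALT)
#' pair equals the panel's (ref, alt) the dosage is the alt-allele count of
#' the GT field; when the pair is swapped the dosage is 2 minus that count;
#' any other allele combination (including strand flips, which are not
#' attempted) drops the site. Multi-allelic records are skipped. Missing GT
#' becomes missing dosage.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped) with GT fields.
#' @param sites Panel site table ([validate_sites()]-conformant tibble).
#' @param min_loci Minimum overlapping site count; below 1000 a warning is
#'   raised, below `min_loci` an error.
#' @return A [study_genotypes].
#' @export
read_vcf_genotypes <- function(vcf_path, sites, min_loci = 100L) {
  if (!file.exists(vcf_path)) stop("file not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  if (nrow(fix) == 0) stop("VCF contains no records: ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", vcf_path)
  key_vcf <- paste(fix[, "CHROM"], fix[, "POS"])
  key_panel <- paste(sites$chrom, sites$pos)
  hit <- match(key_vcf, key_panel)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  keep <- which(!is.na(hit) & biallelic)
  if (length(keep) == 0)
    stop("no VCF records overlap the panel sites; check the reference panel ",
         "choice and coordinate system")
  panel_ref <- sites$ref_allele[hit[keep]]
  panel_alt <- sites$alt_allele[hit[keep]]
  same <- fix[keep, "REF"] == panel_ref & fix[keep, "ALT"] == panel_alt
  swap <- fix[keep, "REF"] == panel_alt & fix[keep, "ALT"] == panel_ref
  keep <- keep[same | swap]
  swap <- swap[same | swap]
  if (length(keep) == 0)
    stop("no VCF records overlap the panel sites after allele reconciliation")
  # alt-allele count from GT, tolerant of phased separators
  dose <- function(g) {
    g[is.na(g)] <- "."
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
  }
  M <- ncol(gt)
  D <- matrix(NA_integer_, M, length(keep))
  for (j in seq_along(keep)) {
    d <- dose(gt[keep[j], ])
    if (swap[j]) d <- 2L - d
    D[, j] <- d
  }
  ord <- order(hit[keep])
  D <- D[, ord, drop = FALSE]
  site_index <- hit[keep][ord]
  if (anyDuplicated(site_index)) {
    first <- !duplicated(site_index)
    D <- D[, first, drop = FALSE]
    site_index <- site_index[first]
  }
  if (length(site_index) < min_loci)
    stop(sprintf("only %d sites overlap the panel; need at least %d",
                 length(site_index), min_loci))
  if (length(site_index) < 1000L)
    warning(sprintf("only %d overlapping sites; placements may be unstable",
                    length(site_index)))
  new_study_genotypes(D, colnames(gt), site_index)
}

#' Write study genotypes as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 with GT-only genotype fields, used to export
#' simulated study cohorts as fixtures.
#'
#' @param study A [study_genotypes].
#' @param sites The panel site table the study is indexed against.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_genotypes <- function(study, sites, path) {
  stopifnot(inherits(study, "study_genotypes"))
  s <- sites[study$site_index, ]
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=refplace-simulated",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", study$sample_ids), collapse = "\t")),
             con)
  G <- study$genotypes
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    writeLines(paste(c(s$chrom[j], s$pos[j], s$site_id[j], s$ref_allele[j],
                       s$alt_allele[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pileup matrix
#'
#' The pileup dialect is long-format, one row per covered (sample, site)
#' cell: a header line `sample_id site_id depth ref_count` (tab-separated)
#' followed by data rows; a companion site-error file has header
#' `site_id error_rate`. Sites absent from the panel are dropped with a
#' message reporting the count.
#'
#' @param pileup_path Path to the long-format pileup file.
#' @param siterr_path Path to the per-site error-rate file.
#' @param sites Panel site table.
#' @return A [pileup_matrix].
#' @export
read_pileup <- function(pileup_path, siterr_path, sites) {
  for (p in c(pileup_path, siterr_path))
    if (!file.exists(p)) stop("file not found: ", p)
  pu <- utils::read.table(pileup_path, header = TRUE, sep = "\t",
                          comment.char = "#",
                          colClasses = c("character", "character", "integer",
                                         "integer"))
  names(pu) <- c("sample_id", "site_id", "depth", "ref_count")
  se <- utils::read.table(siterr_path, header = TRUE, sep = "\t",
                          comment.char = "#",
                          colClasses = c("character", "numeric"))
  names(se) <- c("site_id", "error_rate")
  bad <- which(pu$ref_count > pu$depth)
  if (length(bad) > 0)
    stop(sprintf("ref_count > depth for sample %s at site %s in %s",
                 pu$sample_id[bad[1]], pu$site_id[bad[1]], pileup_path))
  known <- pu$site_id %in% sites$site_id
  if (any(!known)) {
    message(sprintf("dropping %d pileup rows at sites absent from the panel",
                    sum(!known)))
    pu <- pu[known, ]
  }
  if (nrow(pu) == 0) stop("no pileup rows overlap the panel sites")
  site_index <- sort(unique(match(pu$site_id, sites$site_id)))
  sample_ids <- unique(pu$sample_id)
  M <- length(sample_ids); Lp <- length(site_index)
  depth <- matrix(0L, M, Lp)
  ref_count <- matrix(0L, M, Lp)
  i <- match(pu$sample_id, sample_ids)
  j <- match(match(pu$site_id, sites$site_id), site_index)
  depth[cbind(i, j)] <- pu$depth
  ref_count[cbind(i, j)] <- pu$ref_count
  err <- se$error_rate[match(sites$site_id[site_index], se$site_id)]
  if (anyNA(err))
    stop("site-error file is missing error rates for some pileup sites")
  new_pileup_matrix(depth, ref_count, err, sample_ids, site_index)
}

#' Write a pileup matrix
#'
#' Inverse of [read_pileup()]; zero-depth cells are omitted.
#'
#' @param pileup A [pileup_matrix].
#' @param sites Panel site table.
#' @param pileup_path,siterr_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pileup <- function(pileup, sites, pileup_path, siterr_path) {
  stopifnot(inherits(pileup, "pileup_matrix"))
  site_ids <- sites$site_id[pileup$site_index]
  idx <- which(pileup$depth > 0, arr.ind = TRUE)
  df <- data.frame(sample_id = pileup$sample_ids[idx[, 1]],
                   site_id = site_ids[idx[, 2]],
                   depth = pileup$depth[idx],
                   ref_count = pileup$ref_count[idx])
  df <- df[order(match(df$sample_id, pileup$sample_ids),
                 match(df$site_id, site_ids)), ]
  utils::write.table(df, pileup_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(site_id = site_ids,
                                error_rate = pileup$error_rate),
                     siterr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pileup = pileup_path, siterr = siterr_path))
}

#' Write a placement table
#'
#' Tab-separated output: sample_id, L_used, reps, t, t_sd, Z,
#' knn_top_population, knn_top_fraction, then PC1..PCK, with full float
#' precision (15 significant digits).
#'
#' @param placements A placement tibble from [place_all()] (or compatible).
#' @param path Output path.
#' @return Invisibly, `path` (so the tibble pipes through).
#' @export
write_placements <- function(placements, path) {
  pc_cols <- grep("^PC[0-9]+$", names(placements), value = TRUE)
  if (nrow(placements) > 0 && length(pc_cols) == 0)
    stop("placement table has no PC columns")
  lead <- c("sample_id", "L_used", "reps", "t", "t_sd", "Z",
            "knn_top_population", "knn_top_fraction")
  lead <- lead[lead %in% names(placements)]
  cols <- c(lead, pc_cols[order(as.integer(sub("PC", "", pc_cols)))])
  out <- placements[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a placement table written by [write_placements()]
#'
#' @param path Path to a `.placements.tsv`.
#' @return A tibble.
#' @export
read_placements <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
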