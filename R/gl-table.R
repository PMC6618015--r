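# Genotype-likelihood table container and BEAGLE-format IO.
#
# Likelihoods are stored as three sites x individuals matrices (L0, L1, L2:
# likelihood of carrying 0, 1 or 2 copies of the derived allele), a site
# tibble (gene, pos), per-individual sex labels and an explicit missingness
# mask. A missing individual-site is flagged, never silently zero-filled;
# where pooled computations need a value, a flat (1/3, 1/3, 1/3) triple is
# used, which is the no-data likelihood.

#' Construct a genotype-likelihood table
#'
#' @param L0,L1,L2 Numeric matrices (sites x individuals) of likelihoods of
#'   0/1/2 copies of the derived allele. Triples need not be normalized.
#' @param sites Tibble with columns `gene` and `pos` (1-based), one row per
#'   likelihood-matrix row.
#' @param sex Character vector (`"male"`/`"female"`), one per individual.
#' @param missing Optional logical matrix marking individual-sites with no
#'   data. Defaults to triples that are all equal (the no-data triple).
#' @return An object of class `gl_table`.
#' @export
gl_table <- function(L0, L1, L2, sites, sex, missing = NULL) {
  stopifnot(is.matrix(L0), identical(dim(L0), dim(L1)),
            identical(dim(L0), dim(L2)))
  sites <- as_tibble(sites)
  if (nrow(sites) != nrow(L0)) {
    stop_invalid("`sites` must have one row per likelihood row")
  }
  if (length(sex) != ncol(L0)) {
    stop_invalid("`sex` must have one label per individual")
  }
  if (!all(sex %in% c("male", "female"))) {
    stop_invalid("`sex` labels must be 'male' or 'female'")
  }
  if (any(L0 < 0 | L1 < 0 | L2 < 0, na.rm = TRUE)) {
    stop_invalid("likelihoods must be nonnegative")
  }
  if (is.null(missing)) {
    missing <- abs(L0 - L1) < 1e-12 & abs(L1 - L2) < 1e-12
  }
  tot <- L0 + L1 + L2
  tot[tot == 0] <- 1
  structure(
    list(L0 = L0 / tot, L1 = L1 / tot, L2 = L2 / tot,
         sites = sites, sex = sex, missing = missing),
    class = "gl_table"
  )
}

#' @export
print.gl_table <- function(x, ...) {
  cat("<gl_table> ", nrow(x$L0), " sites x ", ncol(x$L0), " individuals (",
      sum(x$sex == "male"), " male, ", sum(x$sex == "female"), " female); ",
      round(100 * mean(x$missing), 1), "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.gl_table <- function(x) dim(x$L0)

# subset a gl_table by site rows and/or individuals
gl_subset <- function(gl, sites = NULL, individuals = NULL) {
  s <- sites %||% seq_len(nrow(gl$L0))
  i <- individuals %||% seq_len(ncol(gl$L0))
  gl_table(gl$L0[s, i, drop = FALSE], gl$L1[s, i, drop = FALSE],
           gl$L2[s, i, drop = FALSE], gl$sites[s, , drop = FALSE],
           gl$sex[i], gl$missing[s, i, drop = FALSE])
}

#' Write a genotype-likelihood table in BEAGLE format
#'
#' Plain-text BEAGLE genotype-likelihood layout: `marker`, `allele1`,
#' `allele2`, then three likelihood columns per individual. Markers are
#' encoded `gene_pos`; alleles are coded 0 (ancestral) and 1 (derived).
#' Missing individual-sites are written as the flat triple.
#'
#' @param gl A [gl_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beagle <- function(gl, path) {
  n_ind <- ncol(gl$L0)
  marker <- paste(gl$sites$gene, gl$sites$pos, sep = "_")
  lik <- matrix(0, nrow(gl$L0), 3 * n_ind)
  for (i in seq_len(n_ind)) {
    lik[, 3 * i - 2] <- gl$L0[, i]
    lik[, 3 * i - 1] <- gl$L1[, i]
    lik[, 3 * i]     <- gl$L2[, i]
  }
  m <- gl$missing
  for (i in seq_len(n_ind)) {
    lik[m[, i], (3 * i - 2):(3 * i)] <- 1 / 3
  }
  hdr <- c("marker", "allele1", "allele2",
           paste0("Ind", rep(seq_len(n_ind) - 1, each = 3)))
  out <- cbind(marker, "0", "1", formatC(lik, format = "g", digits = 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BEAGLE genotype-likelihood file
#'
#' @param path BEAGLE file (plain text or gzip).
#' @param sex Character vector of per-individual sex labels
#'   (`"male"`/`"female"`), in file column order.
#' @return A [gl_table]. Markers must be encoded `gene_pos`; triples that
#'   are numerically flat are flagged missing.
#' @export
read_beagle <- function(path, sex) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         name_repair = "unique_quiet")
  if (ncol(raw) < 6 || (ncol(raw) - 3) %% 3 != 0) {
    stop_invalid("malformed BEAGLE file: expected 3 + 3k columns")
  }
  n_ind <- (ncol(raw) - 3) / 3
  if (length(sex) != n_ind) {
    stop_invalid(sprintf("file has %d individuals but %d sex labels given",
                         n_ind, length(sex)))
  }
  marker <- raw[[1]]
  us <- regexpr("_[^_]*$", marker)
  sites <- tibble(
    gene = substr(marker, 1, us - 1),
    pos = as.integer(substr(marker, us + 1, nchar(marker)))
  )
  lik <- as.matrix(raw[, -(1:3)])
  idx <- function(k) 3 * (seq_len(n_ind) - 1) + k
  gl_table(lik[, idx(1), drop = FALSE], lik[, idx(2), drop = FALSE],
           lik[, idx(3), drop = FALSE], sites, sex)
}

#' Filter sites on per-individual data availability
#'
#' A site is dropped when informative (non-missing) individuals number
#' fewer than half of the total -- or, with `per_sex = TRUE`, fewer than
#' half within either sex separately, the mode used for intersexual
#' differentiation so that sex-limited genes are retained.
#'
#' @param gl A [gl_table].
#' @param min_ind_fraction Minimum fraction of informative individuals
#'   (default 0.5 = "half").
#' @param per_sex Apply the rule within each sex separately.
#' @return A filtered [gl_table].
#' @export
filter_sites <- function(gl, min_ind_fraction = 0.5, per_sex = FALSE) {
  inf <- !gl$missing
  if (!per_sex) {
    keep <- rowSums(inf) >= min_ind_fraction * ncol(inf)
  } else {
    m <- gl$sex == "male"
    keep <- rowSums(inf[, m, drop = FALSE]) >= min_ind_fraction * sum(m) &
      rowSums(inf[, !m, drop = FALSE]) >= min_ind_fraction * sum(!m)
  }
  gl_subset(gl, sites = which(keep))
}
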