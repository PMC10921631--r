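write_tsv_commented <- function(df, path, digest = NULL) {
  if (!is.null(digest)) {
    writeLines(paste0("# mrscore manifest_digest: ", digest), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

# base readers parse doubles with exact strtod semantics, which the
# byte-identical round-trip contract relies on
read_table_auto <- function(path) {
  reader <- if (grepl("\\.csv$", path)) utils::read.csv else utils::read.delim
  as_tibble(reader(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE))
}

#' Write and read cohort tables
#'
#' A cohort is persisted as two TSV files sharing an `id` key column:
#' `metadata.tsv` (covariates plus the `nafld` outcome) and `taxa.tsv`
#' (relative abundances, each row summing to 1). Planted simulation truth,
#' when present, goes to `truth.json`. `read_cohort()` validates structure
#' (unique matching ids, numeric abundances, compositional closure) and
#' names the first offending row/column in its errors.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @param digest Optional manifest digest written as a `#` comment header.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   validated `mrs_cohort` tibble.
#' @export
write_cohort <- function(cohort, dir, digest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- covariate_names(cohort)
  tx <- taxa_names(cohort)
  meta <- as_tibble(as.data.frame(cohort)[, c("id", cov, "nafld")])
  taxa <- as_tibble(as.data.frame(cohort)[, c("id", tx)])
  write_tsv_commented(meta, file.path(dir, "metadata.tsv"), digest)
  write_tsv_commented(taxa, file.path(dir, "taxa.tsv"), digest)
  truth <- cohort_truth(cohort)
  if (!is.null(truth)) {
    truth$linear_predictor <- NULL # bulky; reproducible from the seed
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param metadata,taxa Paths to the two tables (or `dir` containing
#'   `metadata.tsv` / `taxa.tsv`).
#' @param renormalize Accept abundance rows whose sum is off by more than
#'   `tol` and close them to 1 instead of failing.
#' @param tol Row-sum tolerance.
#' @export
read_cohort <- function(dir = NULL, metadata = NULL, taxa = NULL,
                        renormalize = FALSE, tol = 1e-6) {
  metadata <- metadata %||% file.path(dir, "metadata.tsv")
  taxa <- taxa %||% file.path(dir, "taxa.tsv")
  meta <- read_table_auto(metadata)
  tx <- read_table_auto(taxa)
  for (nm in list(c("metadata", "id"), c("taxa", "id"))) {
    tab <- if (nm[1] == "metadata") meta else tx
    if (!"id" %in% names(tab)) {
      abort(paste0(nm[1], " table lacks an id column"))
    }
  }
  if (!"nafld" %in% names(meta)) abort("metadata table lacks the outcome column nafld")
  for (tab in list(meta = meta, taxa = tx)) {
    dup <- tab$id[duplicated(tab$id)]
    if (length(dup) > 0) abort(paste0("duplicated id: ", dup[1]))
  }
  if (!setequal(meta$id, tx$id)) {
    odd <- c(setdiff(meta$id, tx$id), setdiff(tx$id, meta$id))
    abort(paste0("metadata and taxa ids do not match 1:1 (first mismatch: ",
                 odd[1], ")"))
  }
  tx <- tx[match(meta$id, tx$id), , drop = FALSE]
  taxa_cols <- setdiff(names(tx), "id")
  non_num <- taxa_cols[!vapply(tx[taxa_cols], is.numeric, TRUE)]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric abundance column: ", non_num[1]))
  }
  tm <- as.matrix(tx[, taxa_cols])
  rs <- rowSums(tm)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    if (renormalize) {
      tm <- tm / rs
      tx[taxa_cols] <- as.data.frame(tm)
    } else {
      abort(paste0("taxa row for id ", meta$id[off[1]], " sums to ",
                   format(rs[off[1]]),
                   "; pass renormalize = TRUE to close rows to 1"))
    }
  }
  cohort <- left_join(meta, tx, by = "id")
  cohort <- dplyr::relocate(cohort, "nafld", .after = dplyr::last_col())
  attr(cohort, "covariate_names") <- setdiff(names(meta), c("id", "nafld"))
  attr(cohort, "taxa_names") <- taxa_cols
  class(cohort) <- c("mrs_cohort", class(cohort))
  validate_cohort(cohort, tol = if (renormalize) 1e-9 else tol)
}

#' Write and read metabolite tables
#'
#' One TSV with an `id` key column and one positive intensity column per
#' metabolite; subclass labels go to a sidecar `metabolite_subclasses.tsv`.
#'
#' @param metabolites Metabolite tibble.
#' @param path Output TSV path.
#' @param digest Optional manifest digest comment.
#' @export
write_metabolites <- function(metabolites, path, digest = NULL) {
  write_tsv_commented(as_tibble(metabolites), path, digest)
  sub <- attr(metabolites, "subclasses")
  if (!is.null(sub)) {
    write_tsv_commented(tibble(metabolite = names(sub), subclass = unname(sub)),
                        file.path(dirname(path), "metabolite_subclasses.tsv"),
                        digest)
  }
  invisible(path)
}

#' @rdname write_metabolites
#' @export
read_metabolites <- function(path) {
  out <- read_table_auto(path)
  if (!"id" %in% names(out)) abort("metabolite table lacks an id column")
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0) abort(paste0("duplicated id: ", dup[1]))
  m <- as.matrix(out[, setdiff(names(out), "id")])
  if (any(!is.finite(m)) || any(m <= 0)) {
    bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)[1, ]
    abort(paste0("metabolite intensities must be positive (first offence: ",
                 "row ", bad[1], ", column ",
                 setdiff(names(out), "id")[bad[2]], ")"))
  }
  sidecar <- file.path(dirname(path), "metabolite_subclasses.tsv")
  if (file.exists(sidecar)) {
    sub <- read_table_auto(sidecar)
    attr(out, "subclasses") <- setNames(sub$subclass, sub$metabolite)
  }
  class(out) <- c("mrs_metabolites", class(out))
  out
}
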