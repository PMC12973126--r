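#' Twin cohort container
#'
#' A `twin_cohort` is a data frame with one row per twin and attributes
#' recording which columns are phenotypes, the timepoint labels, and
#' (for synthetic cohorts) generating provenance. Required columns:
#' `pair_id`, `twin_order` (1 or 2), `zygosity` (`"MZ"`/`"DZ"`), `sex`
#' (`"F"`/`"M"`, shared within a pair — the study design includes
#' same-sex pairs only). Phenotype columns are named
#' `<phenotype>_<timepoint>` (e.g. `wakeups_t1`); any further columns
#' are treated as covariates.
#'
#' @param data data frame, one row per twin.
#' @param phenotypes character vector of phenotype base names.
#' @param timepoints character vector of timepoint labels, default
#'   `c("t1", "t2")`; single-timepoint cohorts use `"t1"`.
#' @param provenance optional list of generating metadata (parameters,
#'   seed, generator name) carried along for reproducibility.
#' @return A `twin_cohort` object (a classed data frame).
#' @export
twin_cohort <- function(data, phenotypes, timepoints = c("t1", "t2"),
                        provenance = NULL) {
  data <- as.data.frame(data)
  req <- c("pair_id", "twin_order", "zygosity", "sex")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  data$zygosity <- toupper(as.character(data$zygosity))
  if (!all(data$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be 'MZ' or 'DZ'")
  if (!all(data$twin_order %in% c(1L, 2L)))
    stop("twin_order must be 1 or 2")
  if (anyDuplicated(data[c("pair_id", "twin_order")]))
    stop("duplicate (pair_id, twin_order) rows")
  for (v in c("zygosity", "sex")) {
    nun <- tapply(data[[v]], data$pair_id, function(x) length(unique(x)))
    if (any(nun > 1))
      stop("co-twins must share ", v)
  }
  pheno_cols <- as.vector(outer(phenotypes, timepoints, paste, sep = "_"))
  pheno_cols <- intersect(pheno_cols, names(data))
  if (length(pheno_cols) == 0L)
    stop("no phenotype columns found for the declared phenotypes/timepoints")
  structure(data,
            phenotypes = phenotypes,
            timepoints = timepoints,
            provenance = provenance,
            class = c("twin_cohort", "data.frame"))
}

#' @export
print.twin_cohort <- function(x, ...) {
  np <- length(unique(x$pair_id))
  nz <- table(x$zygosity[!duplicated(x$pair_id)])
  cat(sprintf("Twin cohort: %d individuals in %d pairs (%s)\n",
              nrow(x), np,
              paste(sprintf("%s: %d", names(nz), as.integer(nz)),
                    collapse = ", ")))
  cat("  phenotypes:", paste(attr(x, "phenotypes"), collapse = ", "), "\n")
  cat("  timepoints:", paste(attr(x, "timepoints"), collapse = ", "), "\n")
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat("  synthetic; generator:", prov$generator %||% "unknown",
        "seed:", prov$seed %||% "NA", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_phenotypes <- function(cohort) attr(cohort, "phenotypes")
cohort_timepoints <- function(cohort) attr(cohort, "timepoints")

#' Generating provenance of a synthetic cohort
#' @param cohort a [twin_cohort()].
#' @return The provenance list, or `NULL` for observed data.
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")

#' Per-pair phenotype matrices
#'
#' Reshapes a twin cohort into per-zygosity matrices with one row per
#' pair. With one column name, each matrix has columns (twin1, twin2);
#' with two (timepoint 1 and 2 columns of the same phenotype), columns
#' are ordered (twin1-t1, twin2-t1, twin1-t2, twin2-t2), the order the
#' bivariate model machinery expects. Missing cells stay `NA`.
#'
#' @param cohort a [twin_cohort()].
#' @param columns one or two phenotype column names.
#' @return A list with elements `MZ` and `DZ`, each a numeric matrix.
#' @export
pair_matrix <- function(cohort, columns) {
  stopifnot(length(columns) %in% 1:2, all(columns %in% names(cohort)))
  out <- list()
  for (z in c("MZ", "DZ")) {
    sub <- cohort[cohort$zygosity == z, , drop = FALSE]
    ids <- unique(sub$pair_id)
    m <- matrix(NA_real_, length(ids), 2L * length(columns))
    rownames(m) <- as.character(ids)
    for (k in seq_along(columns)) {
      for (ord in 1:2) {
        rows <- sub[sub$twin_order == ord, , drop = FALSE]
        m[match(as.character(rows$pair_id), as.character(ids)),
          (k - 1L) * 2L + ord] <- rows[[columns[k]]]
      }
    }
    out[[z]] <- m
  }
  out
}

#' Write / read a twin cohort as tidy CSV plus provenance sidecar
#'
#' The CSV holds one row per twin with all cohort columns; generating
#' provenance (parameters, seed, generator) goes to `<path>.json` so a
#' synthetic cohort round-trips losslessly.
#'
#' @param cohort a [twin_cohort()].
#' @param path CSV file path.
#' @return `write_twin_cohort` returns `path` invisibly;
#'   `read_twin_cohort` returns a [twin_cohort()].
#' @export
write_twin_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  meta <- list(phenotypes = cohort_phenotypes(cohort),
               timepoints = cohort_timepoints(cohort),
               provenance = cohort_provenance(cohort))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_twin_cohort
#' @export
read_twin_cohort <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    twin_cohort(data, phenotypes = meta$phenotypes,
                timepoints = meta$timepoints,
                provenance = meta$provenance)
  } else {
    # infer phenotypes from <name>_t<k> columns
    pc <- grep("_t[0-9]+$", names(data), value = TRUE)
    phen <- unique(sub("_t[0-9]+$", "", pc))
    tps <- unique(sub("^.*_(t[0-9]+)$", "\\1", pc))
    twin_cohort(data, phenotypes = phen, timepoints = sort(tps))
  }
}
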