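#' Construct a connectome object
#'
#' A connectome is a square symmetric region-by-region matrix tagged with
#' its modality: `"SC"` (structural; non-negative, typically sparse) or
#' `"FC"` (functional; correlations in \[-1, 1\]). The diagonal
#' (self-connections) is carried but ignored by every downstream
#' computation.
#'
#' @param mat Square numeric matrix.
#' @param modality `"SC"` or `"FC"`.
#' @param subject_id Subject identifier string.
#' @param measurement Measurement index (>= 1); functional connectomes may
#'   have several per subject.
#' @param tol Absolute symmetrization tolerance: if the maximum asymmetry
#'   is below `tol` the matrix is symmetrized as `(M + t(M))/2`, otherwise
#'   an error is raised (real asymmetry is a data bug, not round-off).
#' @return A matrix of class `"scfc_connectome"` with attributes
#'   `modality`, `subject_id`, `measurement`.
#' @export
connectome <- function(mat, modality = c("SC", "FC"), subject_id = "subj",
                       measurement = 1L, tol = 1e-8) {
  modality <- match.arg(modality)
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != ncol(mat)) {
    stop_scfc("connectome must be a square numeric matrix")
  }
  asym <- max(abs(mat - t(mat)))
  if (asym >= tol) {
    stop_scfc(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g",
                      asym, tol))
  }
  mat <- (mat + t(mat)) / 2
  off <- mat[row(mat) != col(mat)]
  if (modality == "SC" && any(off < 0)) {
    stop_scfc("SC connectome has negative entries")
  }
  if (modality == "FC" && any(abs(off) > 1 + 1e-9)) {
    stop_scfc("FC connectome has entries outside [-1, 1]")
  }
  structure(mat, modality = modality, subject_id = subject_id,
            measurement = as.integer(measurement),
            class = c("scfc_connectome", class(mat)))
}

#' Read a connectome matrix from a delimited text file
#'
#' @param path Path to a whitespace- or comma-delimited dense numeric
#'   matrix with as many rows and columns as the parcellation has regions.
#' @param parcellation An `"scfc_parcellation"`; fixes the expected
#'   dimension and region order.
#' @inheritParams connectome
#' @return An `"scfc_connectome"` matrix.
#' @export
read_connectome <- function(path, parcellation, modality = c("SC", "FC"),
                            subject_id = NULL, measurement = 1L) {
  modality <- match.arg(modality)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(mat) <- NULL
  n <- nrow(parcellation)
  if (nrow(mat) != n || ncol(mat) != n) {
    stop_scfc(sprintf("connectome is %dx%d but parcellation has %d regions",
                      nrow(mat), ncol(mat), n))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("_(SC|FC)_\\d+\\.[^.]+$", "", basename(path))
  }
  connectome(mat, modality, subject_id, measurement)
}

#' Write a connectome matrix to a delimited text file
#'
#' @param conn An `"scfc_connectome"` (or plain square matrix).
#' @param path Output path; tab-delimited, full double precision.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(format(unclass(conn), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @noRd
RELATIONSHIP_LABELS <- c("MZ_twin", "DZ_twin", "full_sibling", "singleton")

#' @noRd
validate_pedigree <- function(ped) {
  required <- c("subject_id", "family_id", "relationship")
  missing <- setdiff(required, names(ped))
  if (length(missing)) {
    stop_scfc("pedigree is missing column(s): ",
              paste(missing, collapse = ", "))
  }
  if (!"twin_pair_id" %in% names(ped)) ped$twin_pair_id <- NA_character_
  if (anyDuplicated(ped$subject_id)) {
    stop_scfc("duplicated subject_id in pedigree")
  }
  bad <- setdiff(unique(ped$relationship), RELATIONSHIP_LABELS)
  if (length(bad)) {
    stop_scfc("unknown relationship code(s): ", paste(bad, collapse = ", "),
              " (only MZ_twin, DZ_twin, full_sibling, singleton are modelled)")
  }
  is_twin <- ped$relationship %in% c("MZ_twin", "DZ_twin")
  if (any(is_twin & (is.na(ped$twin_pair_id) | ped$twin_pair_id == ""))) {
    stop_scfc("twin without twin_pair_id")
  }
  for (tp in unique(ped$twin_pair_id[is_twin])) {
    members <- ped[!is.na(ped$twin_pair_id) & ped$twin_pair_id == tp, ]
    if (nrow(members) != 2L) {
      stop_scfc("twin_pair_id '", tp, "' has ", nrow(members),
                " member(s); twins need exactly one co-twin")
    }
    if (length(unique(members$family_id)) != 1L ||
        length(unique(members$relationship)) != 1L) {
      stop_scfc("twin pair '", tp, "' spans families or zygosities")
    }
  }
  singles <- ped$family_id[ped$relationship == "singleton"]
  fam_sizes <- table(ped$family_id)
  if (any(fam_sizes[as.character(singles)] != 1L)) {
    stop_scfc("singleton sharing a family with other subjects")
  }
  ped$subject_id <- as.character(ped$subject_id)
  ped$family_id <- as.character(ped$family_id)
  class(ped) <- c("scfc_pedigree", "data.frame")
  ped
}

#' Read a pedigree table
#'
#' The pedigree encodes family structure with the four relationship
#' classes the variance-components model distinguishes: monozygotic twin,
#' dizygotic twin, full sibling and singleton. Members of one `family_id`
#' are treated as sharing parents (common environment). Other relationship
#' codes (half-siblings, parents) are rejected because the kinship kernel
#' is defined only for these classes.
#'
#' @param path Tab-delimited file with header columns `subject_id`,
#'   `family_id`, `relationship` and (for twins) `twin_pair_id`.
#' @return A data frame of class `"scfc_pedigree"`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_pedigree(ped)
}

#' Subset a pedigree to a set of subjects
#'
#' Keeps the named subjects and repairs relationship codes so the result
#' is a valid pedigree: a twin whose co-twin was removed is demoted to
#' `full_sibling` if other family members remain, otherwise to
#' `singleton` (its genetic and environmental kernels with the remaining
#' subjects are unchanged by the demotion).
#'
#' @param pedigree An `"scfc_pedigree"`.
#' @param subject_ids Character vector of subjects to keep.
#' @return An `"scfc_pedigree"` with `length(intersect(...))` rows.
#' @export
subset_pedigree <- function(pedigree, subject_ids) {
  ped <- as.data.frame(pedigree)
  ped <- ped[ped$subject_id %in% subject_ids, , drop = FALSE]
  fam_sizes <- table(ped$family_id)
  for (i in seq_len(nrow(ped))) {
    rel <- ped$relationship[i]
    fam_n <- fam_sizes[[ped$family_id[i]]]
    if (rel %in% c("MZ_twin", "DZ_twin")) {
      tp <- ped$twin_pair_id[i]
      n_pair <- sum(!is.na(ped$twin_pair_id) & ped$twin_pair_id == tp)
      if (n_pair != 2L) {
        ped$relationship[i] <- if (fam_n > 1L) "full_sibling" else
          "singleton"
        ped$twin_pair_id[i] <- NA_character_
      }
    } else if (rel == "full_sibling" && fam_n == 1L) {
      ped$relationship[i] <- "singleton"
    }
  }
  rownames(ped) <- NULL
  validate_pedigree(ped)
}

#' @noRd
COHORT_COLUMNS <- c("age", "sex", "education", "cognition", "icv",
                    "motion", "handedness")

#' Read a cohort covariate table
#'
#' @param path Tab-delimited file with header column `subject_id` plus any
#'   of `age` (years), `sex` (`female`/`male`), `education` (years),
#'   `cognition` (total composite score), `icv` (intracranial volume,
#'   mm^3), `motion` (mean framewise displacement, mm), `handedness`
#'   (score). Missing values are permitted here; analyses that require a
#'   column error if it contains missing entries.
#' @return A data frame of class `"scfc_cohort"`.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(cohort)) {
    stop_scfc("cohort table is missing column 'subject_id'")
  }
  if ("sex" %in% names(cohort)) {
    bad <- setdiff(unique(stats::na.omit(cohort$sex)), c("female", "male"))
    if (length(bad)) stop_scfc("unknown sex value(s): ",
                               paste(bad, collapse = ", "))
  }
  cohort$subject_id <- as.character(cohort$subject_id)
  class(cohort) <- c("scfc_cohort", "data.frame")
  cohort
}

#' Read a phenotype table
#'
#' A phenotype table holds one regional phenotype (coupling, node
#' strength, or a simulated trait) in long-by-measurement layout: one row
#' per (subject, measurement), one column per region.
#'
#' @param path Tab-delimited file with header columns `subject_id`,
#'   `measurement`, then one column per region.
#' @param parcellation Optional parcellation; if given, the region column
#'   count is checked against it.
#' @return A data frame of class `"scfc_phenotypes"`.
#' @export
read_phenotypes <- function(path, parcellation = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  as_phenotype_table(tab, parcellation)
}

#' @noRd
as_phenotype_table <- function(tab, parcellation = NULL) {
  required <- c("subject_id", "measurement")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop_scfc("phenotype table is missing column(s): ",
              paste(missing, collapse = ", "))
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$measurement <- as.integer(tab$measurement)
  if (any(tab$measurement < 1L)) stop_scfc("measurement index must be >= 1")
  if (anyDuplicated(tab[c("subject_id", "measurement")])) {
    stop_scfc("duplicated (subject_id, measurement) row")
  }
  if (!is.null(parcellation) &&
      ncol(tab) - 2L != nrow(parcellation)) {
    stop_scfc(sprintf("phenotype table has %d region columns, expected %d",
                      ncol(tab) - 2L, nrow(parcellation)))
  }
  class(tab) <- c("scfc_phenotypes", "data.frame")
  tab
}

#' Write a table to tab-delimited text
#'
#' Writes with enough precision that `write_table()` followed by the
#' matching reader is the identity (bit-exact for integers and strings,
#' within 1e-12 relative for reals).
#'
#' @param table A data frame (parcellation, pedigree, cohort, phenotype or
#'   plain).
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
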