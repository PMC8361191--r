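#' @noRd
NETWORK_LABELS <- c("VIS", "SOM", "DATTN", "VATTN", "LIM", "FPN", "DMN",
                    "SUB", "CER/BS")

#' @noRd
HEMISPHERE_LABELS <- c("left", "right", "midline")

#' @noRd
validate_parcellation <- function(parc) {
  required <- c("region_id", "label", "hemisphere", "network", "x", "y", "z")
  missing <- setdiff(required, names(parc))
  if (length(missing)) {
    stop_scfc("parcellation is missing column(s): ",
              paste(missing, collapse = ", "))
  }
  if (anyDuplicated(parc$region_id)) {
    stop_scfc("duplicated region_id in parcellation")
  }
  bad_net <- setdiff(unique(parc$network), NETWORK_LABELS)
  if (length(bad_net)) {
    stop_scfc("unknown network label(s): ", paste(bad_net, collapse = ", "))
  }
  bad_hemi <- setdiff(unique(parc$hemisphere), HEMISPHERE_LABELS)
  if (length(bad_hemi)) {
    stop_scfc("unknown hemisphere label(s): ",
              paste(bad_hemi, collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    if (!is.numeric(parc[[col]]) || anyNA(parc[[col]])) {
      stop_scfc("non-numeric centroid coordinate in column '", col, "'")
    }
  }
  if (length(unique(parc$network)) > length(NETWORK_LABELS)) {
    stop_scfc("more than ", length(NETWORK_LABELS), " distinct networks")
  }
  class(parc) <- c("scfc_parcellation", "data.frame")
  parc
}

#' Read a parcellation table
#'
#' Reads the region metadata table that defines the region order used by
#' every downstream computation: one row per region with its identifier,
#' label, hemisphere, functional-network assignment and centroid
#' coordinates in millimetres.
#'
#' @param path Path to a tab-delimited file with header columns
#'   `region_id`, `label`, `hemisphere`, `network`, `x`, `y`, `z`.
#' @return A data frame of class `"scfc_parcellation"`. Row order of the
#'   file fixes region order; `region_id` values are kept verbatim for
#'   joins.
#' @seealso [default_parcellation()] for the packaged synthetic scheme.
#' @export
read_parcellation <- function(path) {
  parc <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  for (col in c("x", "y", "z")) {
    if (col %in% names(parc) && !is.numeric(parc[[col]])) {
      suppressWarnings(num <- as.numeric(parc[[col]]))
      if (anyNA(num)) stop_scfc("non-numeric centroid in column '", col, "'")
      parc[[col]] <- num
    }
  }
  validate_parcellation(parc)
}

#' Default synthetic parcellation
#'
#' A deterministic synthetic parcellation scheme with 392 regions grouped
#' into nine networks: the seven canonical cortical resting-state networks
#' (visual, somatomotor, dorsal attention, ventral attention, limbic,
#' frontoparietal, default mode) plus subcortex and cerebellum/brainstem.
#' Network sizes are unequal (22 to 79 regions), mirroring the imbalance of
#' functionally defined atlases. Centroids are synthetic coordinates with
#' hemisphere-consistent signs; they carry no anatomical meaning beyond
#' providing a distance covariate.
#'
#' @param n_regions Total number of regions; network sizes are scaled
#'   proportionally from the 392-region default.
#' @return A `"scfc_parcellation"` data frame with `n_regions` rows.
#' @export
default_parcellation <- function(n_regions = 392L) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 9L) {
    stop_scfc("'n_regions' must be an integer >= 9")
  }
  base_sizes <- c(VIS = 60L, SOM = 55L, DATTN = 35L, VATTN = 30L,
                  LIM = 22L, FPN = 50L, DMN = 79L, SUB = 31L,
                  `CER/BS` = 30L)
  if (n_regions == 392L) {
    sizes <- base_sizes
  } else {
    sizes <- pmax(1L, as.integer(round(base_sizes * n_regions / 392)))
    # fix rounding drift on the largest network
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] +
      (n_regions - sum(sizes))
  }
  network <- rep(names(base_sizes), sizes)
  hemisphere <- unlist(lapply(sizes, function(k) {
    rep_len(c("left", "right"), k)
  }), use.names = FALSE)
  # midline slots for a few subcortical/brainstem structures
  sub_idx <- which(network %in% c("SUB", "CER/BS"))
  hemisphere[sub_idx[seq_len(min(6L, length(sub_idx)))]] <- "midline"
  centroid <- with_seed(4392L, {
    x <- stats::runif(n_regions, 10, 70)
    x[hemisphere == "left"] <- -x[hemisphere == "left"]
    x[hemisphere == "midline"] <- stats::runif(sum(hemisphere == "midline"),
                                               -2, 2)
    cbind(x = x,
          y = stats::runif(n_regions, -100, 70),
          z = stats::runif(n_regions, -50, 80))
  })
  parc <- data.frame(
    region_id = seq_len(n_regions) - 1L,
    label = sprintf("%s_%03d", gsub("/", "_", network),
                    stats::ave(seq_along(network), network, FUN = seq_along)),
    hemisphere = hemisphere,
    network = network,
    x = round(centroid[, "x"], 2),
    y = round(centroid[, "y"], 2),
    z = round(centroid[, "z"], 2),
    stringsAsFactors = FALSE
  )
  validate_parcellation(parc)
}

#' @export
print.scfc_parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions, %d networks\n",
              nrow(x), length(unique(x$network))))
  tab <- table(x$network)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
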