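BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Side-chain centroid per residue
#'
#' The residue centroid is the arithmetic mean of its side-chain atom
#' coordinates; residues without side-chain atoms (glycine) fall back to
#' the C-alpha position, recorded in the `ca_fallback` column.
#'
#' @param atoms atom table from [read_pdb_atoms()] (`resno`, `resid`,
#'   `elety`, `x`, `y`, `z`).
#' @return data.frame `resno`, `resid`, `x`, `y`, `z`, `ca_fallback`.
#' @export
residue_centroids <- function(atoms) {
  rows <- lapply(split(atoms, atoms$resno), function(a) {
    side <- a[!a$elety %in% BACKBONE_ATOMS, ]
    fallback <- nrow(side) == 0
    if (fallback) {
      side <- a[a$elety == "CA", ]
      if (nrow(side) == 0)
        stop("residue ", a$resno[1], " has neither side-chain atoms nor CA")
    }
    data.frame(resno = a$resno[1], resid = a$resid[1],
               x = mean(side$x), y = mean(side$y), z = mean(side$z),
               ca_fallback = fallback)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$resno), ]
  rownames(out) <- NULL
  out
}

#' Protein centroid and per-residue distances
#'
#' The protein centroid approximates the centre of mass as the mean of all
#' side-chain centroids; distances are direct through-space Euclidean
#' distances in angstroms.
#'
#' @param centroids output of [residue_centroids()].
#' @return list: `centroid` (length-3 numeric), `distances` (data.frame
#'   `resno`, `distance`).
#' @export
protein_centroid <- function(centroids) {
  stopifnot(nrow(centroids) >= 1)
  cm <- c(x = mean(centroids$x), y = mean(centroids$y), z = mean(centroids$z))
  d <- sqrt((centroids$x - cm["x"])^2 + (centroids$y - cm["y"])^2 +
              (centroids$z - cm["z"])^2)
  list(centroid = cm,
       distances = data.frame(resno = centroids$resno, distance = d))
}

#' Burial classification from accessible surface area
#'
#' The accessible proportion is mean SASA over mean residue surface area;
#' a residue is buried when the proportion is strictly below the threshold
#' (default 25 percent).
#'
#' @param mean_sasa mean solvent-accessible surface area (A^2).
#' @param mean_residue_surface_area mean total residue surface area (A^2);
#'   must be positive.
#' @param threshold burial threshold on the proportion.
#' @return data.frame `sasa_proportion`, `buried`.
#' @export
burial <- function(mean_sasa, mean_residue_surface_area, threshold = 0.25) {
  if (any(mean_residue_surface_area <= 0))
    stop("residue surface area must be positive")
  prop <- mean_sasa / mean_residue_surface_area
  data.frame(sasa_proportion = prop, buried = prop < threshold)
}

#' Modal functional class per residue
#'
#' The most frequent SGE class among the missense calls at each residue;
#' ties are broken by severity, fast > slow > enriched > unchanged.
#'
#' @param calls data.frame `residue`, `sge_class` (one row per missense
#'   call).
#' @return data.frame `residue`, `modal_class`.
#' @export
modal_class_per_residue <- function(calls) {
  severity <- c(fast_depleting = 1, slow_depleting = 2, enriched = 3,
                unchanged = 4, depleting = 2.5)
  rows <- lapply(split(calls$sge_class, calls$residue), function(cl) {
    tab <- table(cl)
    top <- names(tab)[tab == max(tab)]
    top[order(severity[top])][1]
  })
  data.frame(residue = as.integer(names(rows)),
             modal_class = unname(unlist(rows)))
}
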