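#' Receptor topology annotation
#'
#' Labels every receptor residue with its secondary-structure segment
#' (TM1-TM7, ECL1-3, ICL1-3, NTERM/CTERM) and records the conserved ECL2
#' cysteine that forms the disulfide bridge to TM3. Segment ranges are
#' author numbering, inclusive, and must be contiguous in sequence.
#'
#' @param segments A data frame with columns `label`, `start`, `end`
#'   (residue numbers, inclusive).
#' @param ecl2_cysteine Residue number of the conserved ECL2 cysteine.
#' @param chain Chain identifier the annotation applies to.
#' @return An object of class `pf_topology`.
#' @export
pf_topology <- function(segments, ecl2_cysteine, chain = "A") {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("label", "start", "end") %in% names(segments)))
  allowed <- c(paste0("TM", 1:7), paste0("ECL", 1:3), paste0("ICL", 1:3),
               "NTERM", "CTERM")
  bad <- setdiff(segments$label, allowed)
  if (length(bad) > 0) {
    abort_pf(paste0("unknown segment label(s): ", paste(bad, collapse = ", ")),
             "annotation_error")
  }
  segments <- dplyr::arrange(segments, .data$start)
  if (any(segments$end < segments$start)) {
    abort_pf("segment with end < start", "annotation_error")
  }
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)])) {
    abort_pf("overlapping topology segments", "annotation_error")
  }
  ecl2 <- segments[segments$label == "ECL2", ]
  if (nrow(ecl2) == 1 &&
      (ecl2_cysteine < ecl2$start || ecl2_cysteine > ecl2$end)) {
    abort_pf("ecl2_cysteine lies outside the ECL2 segment", "annotation_error")
  }
  structure(list(segments = segments, ecl2_cysteine = as.integer(ecl2_cysteine),
                 chain = chain),
            class = "pf_topology")
}

#' Read a topology annotation from JSON
#'
#' Expected shape:
#' `{"chain": "A", "segments": [{"label": "TM1", "start": 1, "end": 35},
#' ...], "ecl2_cysteine": 176}`.
#'
#' @param path JSON file path.
#' @return A [pf_topology()].
#' @export
read_topology_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  pf_topology(j$segments, j$ecl2_cysteine, chain = j$chain %||% "A")
}

#' Read a Ballesteros-Weinstein anchor map from JSON
#'
#' Expected shape: `{"1.48": "A:45", "2.51": "A:52", ...}`; values are
#' `chain:resnum` residue identifiers.
#'
#' @param path JSON file path.
#' @return Named character vector.
#' @export
read_bw_map <- function(path) {
  unlist(jsonlite::fromJSON(path))
}

# Segment label per residue number; NA when unlabeled.
segment_label <- function(topology, res_num) {
  seg <- topology$segments
  lab <- rep(NA_character_, length(res_num))
  for (i in seq_len(nrow(seg))) {
    lab[res_num >= seg$start[i] & res_num <= seg$end[i]] <- seg$label[i]
  }
  lab
}

bw_anchor_positions <- c("1.48", "2.51", "3.38", "4.51", "5.50", "6.43", "7.45")

#' Partition the transmembrane bundle into extracellular and cytoplasmic
#' regions
#'
#' The cut points are seven user-supplied residues at Ballesteros-Weinstein
#' positions 1.48, 2.51, 3.38, 4.51, 5.50, 6.43 and 7.45, one per helix,
#' sitting below the orthosteric pocket. For TM2-TM7 every residue on the
#' extracellular side of the helix's anchor joins the mobile extracellular
#' region; the anchor itself and everything below, plus the whole of TM1,
#' stay in the static cytoplasmic region. Extracellular loops present in
#' the structure are extracellular; intracellular loops and termini are
#' cytoplasmic. The extracellular end of each helix is inferred from
#' canonical class-A membrane topology: even-numbered helices run
#' intracellular-to-extracellular in sequence, odd-numbered the reverse.
#'
#' @param complex A [pf_complex()].
#' @param topology A [pf_topology()] covering every receptor residue.
#' @param bw_map Named character vector mapping all seven anchor positions
#'   (e.g. `"2.51"`) to `chain:resnum` residue identifiers.
#' @return A list with `extracellular` and `cytoplasmic` residue-id sets
#'   (disjoint, jointly covering the receptor) and the resolved `anchors`.
#' @export
partition_regions <- function(complex, topology, bw_map) {
  missing <- setdiff(bw_anchor_positions, names(bw_map))
  if (length(missing) > 0) {
    abort_pf(paste0("BW map is missing anchor position(s): ",
                    paste(missing, collapse = ", ")), "mapping_error")
  }
  ids <- receptor_residues(complex)
  anchors <- bw_map[bw_anchor_positions]
  absent <- anchors[!anchors %in% ids]
  if (length(absent) > 0) {
    abort_pf(paste0("BW anchor(s) not present in complex: ",
                    paste(names(absent), collapse = ", ")), "mapping_error")
  }
  nums <- as.integer(sub("^.*:", "", ids))
  lab <- segment_label(topology, nums)
  if (anyNA(lab)) {
    abort_pf(paste0("residue(s) without topology label: ",
                    paste(ids[is.na(lab)], collapse = ", ")),
             "annotation_error")
  }
  anchor_num <- as.integer(sub("^.*:", "", anchors))
  names(anchor_num) <- bw_anchor_positions

  extra <- rep(FALSE, length(ids))
  extra[grepl("^ECL", lab)] <- TRUE
  for (h in 2:7) {
    tm <- lab == paste0("TM", h)
    a <- anchor_num[[bw_anchor_positions[h]]]
    if (h %% 2 == 0) {
      extra[tm & nums > a] <- TRUE  # EC end is the C-terminal end
    } else {
      extra[tm & nums < a] <- TRUE  # EC end is the N-terminal end
    }
  }
  list(extracellular = ids[extra], cytoplasmic = ids[!extra],
       anchors = anchors)
}

#' Delete the flexible loops, keeping ECL2-distal
#'
#' Removes ECL1, ECL3, all intracellular loops and the termini, together
#' with the part of ECL2 upstream of its conserved cysteine. The cysteine
#' itself (it anchors the disulfide to TM3) and everything downstream of it
#' (toward TM5) are retained, as are all transmembrane residues. The
#' operation is idempotent.
#'
#' @param complex A [pf_complex()].
#' @param topology A [pf_topology()] covering every receptor residue.
#' @return A trimmed [pf_complex()].
#' @export
trim_loops <- function(complex, topology) {
  at <- complex$receptor
  lab <- segment_label(topology, at$res_num)
  if (anyNA(lab)) {
    abort_pf(paste0("residue(s) without topology label: ",
                    paste(unique(res_id(at$chain, at$res_num, at$ins)[is.na(lab)]),
                          collapse = ", ")), "annotation_error")
  }
  drop <- lab %in% c("ECL1", "ECL3", "ICL1", "ICL2", "ICL3", "NTERM", "CTERM") |
    (lab == "ECL2" & at$res_num < topology$ecl2_cysteine)
  out <- complex
  out$receptor <- at[!drop, ]
  out
}
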