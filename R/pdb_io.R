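#' Secondary structure assignments
#'
#' A 3-state per-residue secondary structure assignment over the alphabet
#' `{H, E, C}` (helix, strand, linker/coil). DSSP-style 8-state strings are
#' collapsed as H,G,I -> H; E,B -> E; everything else -> C. The derived
#' `sections` table partitions the residue range into maximal same-label runs.
#'
#' @param labels character vector of single-letter states (one per residue),
#'   or a single string.
#' @return an object of class `ss_assignment`: list with `labels` and
#'   `sections` (data frame `label`, `start`, `end`).
#' @export
#' @examples
#' ss_assignment("CHHHC")$sections
ss_assignment <- function(labels) {
  if (length(labels) == 1L && nchar(labels[1L]) > 1L) {
    labels <- strsplit(labels, "")[[1L]]
  }
  labels <- toupper(as.character(labels))
  if (length(labels) == 0L) stop("empty secondary structure assignment")
  labels[labels %in% c("H", "G", "I")] <- "H"
  labels[labels %in% c("E", "B")] <- "E"
  labels[!labels %in% c("H", "E")] <- "C"
  structure(list(labels = labels, sections = ss_runs(labels)),
            class = "ss_assignment")
}

ss_runs <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(label = r$values,
             start = end - r$lengths + 1L,
             end = end,
             stringsAsFactors = FALSE)
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> %d residues, %d sections: %s\n",
              length(x$labels), nrow(x$sections),
              paste0(x$sections$label, collapse = "")))
  invisible(x)
}

#' @export
length.ss_assignment <- function(x) length(x$labels)

#' Clean singleton secondary structure elements
#'
#' Experimental assignments occasionally contain single-residue helices or
#' strands sandwiched between linker sections; these inflate the apparent
#' number of secondary structure elements and hence the smoothed-curve
#' length. Every `H` or `E` run of length 1 whose neighbours on both sides
#' are `C` runs (or the chain boundary) is relabelled `C`. The operation is
#' idempotent and never increases the number of sections.
#'
#' @param ss an [ss_assignment].
#' @return the cleaned [ss_assignment].
#' @export
#' @examples
#' clean_ss(ss_assignment("CHC"))
clean_ss <- function(ss) {
  stopifnot(inherits(ss, "ss_assignment"))
  labels <- ss$labels
  runs <- ss$sections
  nr <- nrow(runs)
  for (k in seq_len(nr)) {
    if (runs$label[k] %in% c("H", "E") &&
        runs$end[k] == runs$start[k]) {
      left_c <- k == 1L || runs$label[k - 1L] == "C"
      right_c <- k == nr || runs$label[k + 1L] == "C"
      if (left_c && right_c) labels[runs$start[k]] <- "C"
    }
  }
  ss_assignment(labels)
}

#' Read a PSIPRED vertical .ss2 secondary structure file
#'
#' Parses the PSIPRED "VFORMAT" layout: one line per residue holding the
#' residue index, amino acid, predicted state and three class confidences.
#' Comment (`#`) and blank lines are skipped; states are uppercased and
#' mapped into `{H, E, C}`; confidences are discarded.
#'
#' @param path file path, or a character vector of lines.
#' @return an [ss_assignment].
#' @export
read_ss_psipred <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
  else as.character(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty PSIPRED .ss2 input")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(fields, length, 0L) < 3L
  if (any(bad)) {
    stop("malformed .ss2 line(s): ", paste(which(bad)[1L], collapse = ", "))
  }
  states <- vapply(fields, `[[`, "", 3L)
  ss_assignment(states)
}

#' Read a C-alpha backbone from PDB-format text
#'
#' Extracts the C-alpha trace of one chain from standard PDB ATOM records
#' (heteroatoms excluded). By default the first MODEL is used, and where a
#' residue carries alternate locations only the first encountered is kept.
#' Residues appear in file (residue) order, insertion codes included. An edge
#' whose C-alpha separation exceeds 4.5 Angstrom is flagged as a chain break
#' (attribute `breaks` on the result) with a warning; breaks are treated as
#' immovable section boundaries by [skmt()].
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param chain chain identifier (single character). `NULL` picks the first
#'   chain present.
#' @param model model number to read (default: first model in the file).
#' @return a [discrete_curve] with attributes `breaks` (integer edge indices)
#'   and `source` (list: id, chain, model).
#' @export
read_ca_backbone <- function(pdb_source, chain = NULL, model = 1L) {
  lines <- if (length(pdb_source) == 1L && file.exists(pdb_source)) {
    readLines(pdb_source)
  } else as.character(pdb_source)

  # restrict to the requested model where MODEL records exist
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) > 0L) {
    model_no <- suppressWarnings(as.integer(substr(lines[model_starts],
                                                   11L, 14L)))
    pick <- if (is.na(model) || model %in% model_no) {
      which(model_no == model)[1L]
    } else 1L
    if (is.na(pick)) pick <- 1L
    from <- model_starts[pick]
    ends <- grep("^ENDMDL", lines)
    to <- ends[ends > from][1L]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
  }

  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) stop("no ATOM records in PDB input")
  name <- trimws(substr(atom, 13L, 16L))
  ca <- atom[name == "CA"]
  if (length(ca) == 0L) stop("no C-alpha atoms in PDB input")

  ch <- substr(ca, 22L, 22L)
  chains <- unique(ch)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain, paste(chains, collapse = ", ")))
  }
  ca <- ca[ch == chain]

  altloc <- substr(ca, 17L, 17L)
  resseq <- trimws(substr(ca, 23L, 26L))
  icode <- substr(ca, 27L, 27L)
  resid <- paste0(resseq, icode)
  keep <- !duplicated(resid)            # first altloc per residue
  ca <- ca[keep]

  pts <- cbind(as.numeric(substr(ca, 31L, 38L)),
               as.numeric(substr(ca, 39L, 46L)),
               as.numeric(substr(ca, 47L, 54L)))
  if (anyNA(pts)) stop("unparseable coordinates in PDB ATOM records")
  curve <- discrete_curve(pts, label = sprintf("chain %s", chain))

  steps <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
  breaks <- which(steps > 4.5)
  if (length(breaks) > 0L) {
    warning(sprintf("%d chain break(s) flagged (C-alpha separation > 4.5 A) at edge(s) %s",
                    length(breaks), paste(breaks, collapse = ", ")))
  }
  attr(curve, "breaks") <- as.integer(breaks)
  attr(curve, "source") <- list(id = "", chain = chain,
                                model = as.integer(model))
  curve
}

#' Write a curve as a minimal PDB file
#'
#' Pseudo C-alpha ATOM records (glycine residues, chain A), chiefly for
#' visualization of smoothed curves and for coordinate round-trip tests.
#' Coordinates are written at PDB precision (3 decimals).
#'
#' @param curve a [discrete_curve] or [smoothed_curve].
#' @param path output file path.
#' @param chain chain identifier to write.
#' @export
write_pdb <- function(curve, path, chain = "A") {
  pts <- curve_points(curve)
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(pts)), chain, seq_len(nrow(pts)),
    pts[, 1L], pts[, 2L], pts[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Pair a backbone curve with a secondary structure assignment
#'
#' Validates that the two inputs describe the same number of residues,
#' applies [clean_ss()] (singleton removal is part of the standard smoothing
#' pipeline) and bundles them into a labelled backbone ready for [skmt()].
#'
#' @param curve a [discrete_curve] of C-alpha coordinates.
#' @param ss an [ss_assignment] (or a plain 3-state string).
#' @param source free-text provenance tag.
#' @return an object of class `labeled_backbone`: list with `curve`, `ss`
#'   (cleaned) and `source`; chain-break edges are carried over from the
#'   curve's `breaks` attribute.
#' @export
pair_backbone <- function(curve, ss, source = "") {
  if (!inherits(ss, "ss_assignment")) ss <- ss_assignment(ss)
  n <- n_points(curve)
  if (n != length(ss$labels)) {
    stop(sprintf("backbone has %d residues but assignment has %d",
                 n, length(ss$labels)))
  }
  breaks <- attr(curve, "breaks")
  if (is.null(breaks)) breaks <- integer(0)
  structure(list(curve = curve, ss = clean_ss(ss),
                 breaks = as.integer(breaks),
                 source = as.character(source)[1L]),
            class = "labeled_backbone")
}

#' @export
print.labeled_backbone <- function(x, ...) {
  cat(sprintf("<labeled_backbone> %d residues, %d sections%s\n",
              n_points(x$curve), nrow(x$ss$sections),
              if (length(x$breaks)) sprintf(", %d chain break(s)",
                                            length(x$breaks)) else ""))
  invisible(x)
}
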