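#' Construct a C-alpha structure record
#'
#' A `structure_record` holds one parsed protein chain at C-alpha
#' resolution: residue identifiers (author numbering, with any insertion
#' code appended, e.g. `"52A"`), one-letter residue codes, and an N x 3
#' coordinate matrix in Angstrom, plus member-level metadata.
#'
#' @param member_id character scalar, e.g. a PDB identifier.
#' @param chain_id one-character chain identifier.
#' @param residue_ids character vector of unique residue identifiers.
#' @param residue_codes character vector of one-letter amino-acid codes
#'   (`"X"` for non-standard residues).
#' @param ca_coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param species character scalar (may be `""`).
#' @param state_label one of `"active"`, `"inactive"`, `"none"`.
#' @param segments optional character vector annotating each position
#'   (e.g. `"helix"` / `"loop"`), used by the synthetic generator.
#' @return an object of class `structure_record`.
#' @export
structure_record <- function(member_id, chain_id, residue_ids, residue_codes,
                             ca_coords, species = "", state_label = "none",
                             segments = NULL) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L) stop("'ca_coords' must have 3 columns")
  n <- length(residue_ids)
  if (length(residue_codes) != n || nrow(ca_coords) != n)
    stop("residue_ids, residue_codes and ca_coords must have equal length")
  if (anyDuplicated(residue_ids))
    stop("residue identifiers must be unique within a record")
  if (!state_label %in% c("active", "inactive", "none"))
    stop("state_label must be one of 'active', 'inactive', 'none'")
  if (!is.null(segments) && length(segments) != n)
    stop("'segments' must match the number of residues")
  structure(list(member_id = as.character(member_id),
                 chain_id = as.character(chain_id),
                 residue_ids = as.character(residue_ids),
                 residue_codes = as.character(residue_codes),
                 ca_coords = unname(ca_coords),
                 species = as.character(species),
                 state_label = state_label,
                 segments = segments),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s chain %s: %d residues\n",
              x$member_id, x$chain_id, length(x$residue_ids)))
  cat(" sequence:", abbreviate(record_sequence(x), 60), "\n")
  if (nzchar(x$species)) cat(" species: ", x$species, "\n")
  cat(" state:   ", x$state_label, "\n")
  invisible(x)
}

#' @export
length.structure_record <- function(x) length(x$residue_ids)

#' Parse the C-alpha trace of one chain from PDB-format text
#'
#' Reads `ATOM` records only (HETATM excluded), keeps one CA atom per
#' residue. When alternate locations are present the highest-occupancy
#' altloc is kept, ties going to the alphabetically first altloc.
#' Residues on the chain that have atoms but no CA are dropped with a
#' warning. Non-standard residues with a CA are kept with code `"X"`.
#'
#' @param pdb_text character: PDB-format text (one string or a vector of
#'   lines), or the path to a PDB file.
#' @param chain_id chain to extract.
#' @param member_id,species,state_label metadata attached to the record.
#' @return a [structure_record()].
#' @export
parse_ca_structure <- function(pdb_text, chain_id, member_id = "",
                               species = "", state_label = "none") {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    path <- pdb_text
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb_text, "\n", fixed = TRUE)), path)
  }
  # rm.alt = FALSE: altloc resolution is done here, not by the reader
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found in PDB input")
  chains <- sort(unique(at$chain))
  if (!chain_id %in% chains)
    stop(sprintf("chain '%s' not present; available chains: %s",
                 chain_id, paste(chains, collapse = ", ")))
  at <- at[at$chain == chain_id, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  rid <- paste0(at$resno, at$insert)

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_rid <- rid[at$elety == "CA"]
  if (nrow(ca) == 0L)
    stop(sprintf("chain '%s' has no CA atoms", chain_id))
  no_ca <- setdiff(unique(rid), unique(ca_rid))
  if (length(no_ca) > 0L)
    warning(sprintf("chain %s: %d residue(s) without a CA atom omitted (%s)",
                    chain_id, length(no_ca),
                    paste(utils::head(no_ca, 5), collapse = ", ")))

  # altloc resolution: highest occupancy wins, ties -> first alphabetically
  keep <- integer(0)
  for (r in unique(ca_rid)) {
    idx <- which(ca_rid == r)
    if (length(idx) > 1L) {
      occ <- ca$o[idx]
      occ[is.na(occ)] <- 1
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) best <- best[order(ca$alt[best])][1L]
      idx <- best[1L]
    }
    keep <- c(keep, idx)
  }
  ca <- ca[keep, , drop = FALSE]
  ca_rid <- ca_rid[keep]

  codes <- suppressWarnings(bio3d::aa321(ca$resid))
  codes[is.na(codes) | !codes %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  structure_record(member_id = member_id, chain_id = chain_id,
                   residue_ids = ca_rid, residue_codes = codes,
                   ca_coords = cbind(ca$x, ca$y, ca$z),
                   species = species, state_label = state_label)
}

#' One-letter sequence of a structure record
#'
#' @param record a [structure_record()].
#' @return single character string of one-letter codes.
#' @export
record_sequence <- function(record) {
  if (length(record$residue_codes) == 0L) stop("record is empty")
  paste(record$residue_codes, collapse = "")
}

#' Load and validate a member metadata table
#'
#' Expects CSV with header columns `member_id, chain_id, species,
#' state_label, gene_code`. State labels are lower-cased; anything outside
#' \{active, inactive, none\} is mapped to `"none"` with a warning.
#'
#' @param table_text CSV text or a path to a CSV file.
#' @return a data.frame with one validated row per member.
#' @export
load_metadata <- function(table_text) {
  if (length(table_text) == 1L && !grepl("\n", table_text) &&
      file.exists(table_text)) {
    df <- utils::read.csv(table_text, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    df <- utils::read.csv(textConnection(paste(table_text, collapse = "\n")),
                          stringsAsFactors = FALSE, colClasses = "character")
  }
  required <- c("member_id", "chain_id", "species", "state_label", "gene_code")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$member_id))
    stop("duplicate member_id in metadata: ",
         paste(unique(df$member_id[duplicated(df$member_id)]), collapse = ", "))
  if (any(!nzchar(df$chain_id)))
    stop("every metadata row must have a nonempty chain_id")
  st <- tolower(trimws(df$state_label))
  bad <- !st %in% c("active", "inactive", "none")
  if (any(bad)) {
    warning(sprintf("%d unknown state label(s) mapped to 'none': %s",
                    sum(bad), paste(unique(df$state_label[bad]), collapse = ", ")))
    st[bad] <- "none"
  }
  df$state_label <- st
  df[required]
}

#' Write a structure record as minimal PDB text
#'
#' Emits one fixed-width `ATOM` CA line per residue (PDB precision,
#' 0.001 Angstrom). Unknown one-letter codes are written as `UNK`.
#'
#' @param record a [structure_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record_pdb <- function(record, path) {
  resno <- as.integer(sub("([0-9-]+).*", "\\1", record$residue_ids))
  insert <- sub("^[0-9-]+", "", record$residue_ids)
  res3 <- suppressWarnings(bio3d::aa123(record$residue_codes))
  res3[is.na(res3) | record$residue_codes == "X"] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_along(resno), res3, record$chain_id, resno,
    ifelse(nzchar(insert), insert, " "),
    record$ca_coords[, 1], record$ca_coords[, 2], record$ca_coords[, 3],
    1.00, 0.00)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export record sequences to FASTA
#'
#' @param records list of [structure_record()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_records_fasta <- function(records, path) {
  seqs <- vapply(records, record_sequence, character(1))
  names(seqs) <- vapply(records, function(r) r$member_id, character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}
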