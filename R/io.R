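#' Read identity-versus-time observations from TSV
#'
#' Expects columns `family_id`, `pair_id`, `identity_pct`, `time_gy` and
#' optionally `time_min_gy`, `time_max_gy`; columns already named
#' `identity` / `time` are also accepted.
#'
#' @param path TSV file path.
#' @return Tibble with standardized columns `identity`, `time` (and
#'   `time_min`, `time_max` when present).
#' @export
read_divergence_obs <- function(path) {
  normalize_obs(readr::read_tsv(path, show_col_types = FALSE))
}

#' Write identity-versus-time observations to TSV
#'
#' @param obs Observation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_divergence_obs <- function(obs, path) {
  readr::write_tsv(normalize_obs(obs), path)
  invisible(path)
}

#' Read a (multiple) sequence alignment or sequence set from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a site-fitness table from TSV
#'
#' Expects columns `site` (or `position`) and `mean_fitness` (or
#' `fitness`).
#'
#' @param path TSV file path.
#' @return Tibble with columns `site`, `fitness`.
#' @export
read_site_fitness <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"site" %in% names(d) && "position" %in% names(d)) {
    d <- dplyr::rename(d, site = "position")
  }
  if (!"fitness" %in% names(d) && "mean_fitness" %in% names(d)) {
    d <- dplyr::rename(d, fitness = "mean_fitness")
  }
  stopifnot(all(c("site", "fitness") %in% names(d)))
  d
}

#' Read a MAGE count table from TSV
#'
#' @param path TSV with identifier columns (`mutant_id`, `position`,
#'   `codon`, `aa`, `wt_aa`, `batch`) and one numeric-named column per
#'   time point in hours.
#' @return Tibble in the [mage-fitness] count-table layout.
#' @export
read_mage_counts <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  time_columns(d)  # validates layout
  wt_row_index(d)
  d
}

#' Extract C-alpha coordinates from a PDB file
#'
#' Reads `ATOM` records via the bio3d package and returns one C-alpha per
#' residue for the selected chain, indexed by residue number.
#'
#' @param path PDB file.
#' @param chain Chain identifier (default `"A"`).
#' @return Tibble: `site` (residue number), `x`, `y`, `z`, `aa`
#'   (three-letter residue name).
#' @export
read_ca_coords <- function(path, chain = "A") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading PDB files requires the bio3d package.",
          class = "divlimit_missing_dependency")
  }
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$elety == "CA" & pdb$atom$chain == chain &
    pdb$atom$type == "ATOM"
  at <- pdb$atom[sel, ]
  at <- at[!duplicated(at$resno), ]
  tibble::tibble(site = at$resno, x = at$x, y = at$y, z = at$z, aa = at$resid)
}

#' Read a Newick tree
#'
#' Unrooted inputs are midpoint-rooted so downstream pair selection sees a
#' rooted tree.
#'
#' @param path Newick file.
#' @return A rooted `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (!ape::is.rooted(tr)) {
    if (requireNamespace("phangorn", quietly = TRUE)) {
      tr <- phangorn::midpoint(tr)
    } else {
      # fallback: root on the leaf at one end of the longest path
      dm <- ape::cophenetic.phylo(tr)
      ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
      tr <- ape::root(tr, outgroup = tr$tip.label[ij[1]], resolve.root = TRUE)
    }
  }
  tr
}
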