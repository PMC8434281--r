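# End-to-end orchestration: mine -> torsions -> cluster -> stats -> dimers
# -> summary, as one reproducible run with machine-readable outputs.

#' Build a pipeline run configuration
#'
#' @param input either a named list of \code{zt_structure} objects or a
#'   character vector of structure file paths
#' @param coordination_cutoff zinc coordination cutoff, Angstrom
#' @param max_ca alpha-turn Ca(i)-Ca(i+4) cutoff, Angstrom
#' @param cluster_cutoff GROMOS RMSD cutoff, Angstrom
#' @param max_resolution resolution filter, Angstrom (NA disables it, e.g.
#'   for synthetic inputs carrying nominal resolutions)
#' @param subset atom subset for clustering
#' @param chains optional chain allowlist passed to mining
#' @param out_dir output directory (NULL = no files written)
#' @param seed integer seed recorded with the run
#' @return list of class \code{zt_config}
#' @export
pipeline_config <- function(input, coordination_cutoff = 3.0, max_ca = 7.0,
                            cluster_cutoff = 0.4, max_resolution = 2.4,
                            subset = default_atom_subset(), chains = NULL,
                            out_dir = NULL, seed = 1L) {
  stopifnot(coordination_cutoff > 0, max_ca > 0, cluster_cutoff > 0)
  structure(list(input = input, coordination_cutoff = coordination_cutoff,
                 max_ca = max_ca, cluster_cutoff = cluster_cutoff,
                 max_resolution = max_resolution, subset = subset,
                 chains = chains, out_dir = out_dir, seed = seed),
            class = "zt_config")
}

#' Run the retrostructural analysis pipeline
#'
#' Executes mining, torsion analysis, GROMOS clustering, position
#' statistics and dimer detection over a set of structures, and returns
#' (and optionally writes) a report bundle: motif and torsion tables, the
#' clustering with its per-cluster circular torsion summary, occurrence
#' and propensity tables over the unique sequences, detected
#' pseudo-symmetric pairs, and a summary with every stage's input/output
#' counts.  The partition identity (motifs = sum of cluster sizes +
#' outliers) is asserted on every run.
#'
#' @param config a \code{zt_config} from \code{\link{pipeline_config}}
#' @return list of class \code{zt_report}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "zt_config"))
  structures <- config$input
  if (is.character(structures)) {
    paths <- structures
    structures <- lapply(paths, read_structure)
    names(structures) <- vapply(structures, `[[`, character(1), "id")
  }
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, `[[`, character(1), "id")
  counts <- list(structures_in = length(structures))
  if (!is.na(config$max_resolution)) {
    structures <- resolution_filter(structures, config$max_resolution)
  }
  counts$structures_after_resolution <- length(structures)

  motifs <- list()
  pairs <- list()
  for (s in structures) {
    sites <- find_zinc_sites(s, cutoff = config$coordination_cutoff)
    motifs <- c(motifs, find_cxxhx_motifs(s, sites, chains = config$chains))
    pairs <- c(pairs, find_pseudosymmetric_pairs(s, sites))
  }
  counts$motifs_mined <- length(motifs)
  keep <- vapply(motifs, alpha_turn_filter, logical(1),
                 max_ca = config$max_ca)
  motifs <- motifs[keep]
  counts$motifs_alpha_turn <- length(motifs)

  torsions <- if (length(motifs)) torsion_table(motifs, structures) else NULL
  clustering <- NULL
  summary_tab <- NULL
  if (length(motifs) >= 1) {
    D <- pairwise_rmsd(motifs, structures, subset = config$subset)
    clustering <- gromos_cluster(D, cutoff = config$cluster_cutoff)
    summary_tab <- cluster_summary(clustering, torsions)
    sizes <- vapply(clustering$clusters, function(cl) length(cl$members),
                    integer(1))
    if (sum(sizes) + length(clustering$outliers) != length(motifs))
      stop("run_pipeline: partition identity violated (",
           sum(sizes), " + ", length(clustering$outliers), " != ",
           length(motifs), ")")
    counts$cluster_sizes <- as.integer(sizes)
    counts$outliers <- length(clustering$outliers)
  }
  unique_motifs <- deduplicate_sequences(motifs)
  counts$unique_sequences <- length(unique_motifs)
  occ <- occurrence_table(unique_motifs)
  prop <- propensity_table(occ)
  counts$pseudosymmetric_pairs <- length(pairs)

  report <- structure(list(
    config = config, motifs = motifs, motif_table = motif_table(motifs),
    torsions = torsions, clustering = clustering,
    cluster_summary = summary_tab, occurrences = occ, propensities = prop,
    pairs = pairs, counts = counts), class = "zt_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.zt_report <- function(x, ...) {
  cat("<zt_report>\n")
  cat("  structures:", x$counts$structures_in,
      " motifs:", x$counts$motifs_alpha_turn,
      " unique sequences:", x$counts$unique_sequences, "\n")
  if (!is.null(x$counts$cluster_sizes))
    cat("  clusters:", paste(x$counts$cluster_sizes, collapse = ", "),
        " outliers:", x$counts$outliers, "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    write.table(df, file.path(out_dir, name), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  wt(report$motif_table, "motifs.tsv")
  wt(report$torsions, "torsions.tsv")
  wt(report$cluster_summary, "cluster_summary.tsv")
  occ <- report$occurrences
  occ_df <- data.frame(residue = rownames(occ), occ,
                       check.names = FALSE)
  wt(occ_df, "occurrences.tsv")
  prop <- report$propensities
  prop_df <- data.frame(residue = rownames(prop), round(prop, 3),
                        check.names = FALSE)
  wt(prop_df, "propensities.tsv")
  if (!is.null(report$clustering)) {
    cl <- report$clustering
    jsonlite::write_json(list(
      cutoff = cl$cutoff,
      atom_subset = "backbone N/CA/C of the 5 motif residues + Cys SG + His ND1 + Zn (reconstructed 18-atom subset)",
      clusters = lapply(cl$clusters, function(c)
        list(centroid = c$centroid, members = c$members)),
      outliers = cl$outliers),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE)
  }
  jsonlite::write_json(c(report$counts,
                         list(background = attr(report$propensities,
                                                "background_source"),
                              seed = report$config$seed)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
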