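#' Run one analysis task end to end
#'
#' Unified entry point behind the command-line tool: executes one of the
#' four tasks (plus fixture generation), writes every artifact into
#' `out_dir` and collects a machine-readable JSON run summary listing the
#' resolved parameters, the output-file manifest and the per-task payload
#' (labels / groups / matches / sites).
#'
#' @param task one of `"annotate"`, `"decompose"`, `"generate-library"`,
#'   `"superpose"`, `"make-fixture"`
#' @param params named list of task parameters (see Details)
#' @param out_dir output directory
#' @return the run summary (list), invisibly; written as `summary.json`
#'
#' @details Common parameters: `input` (PDB path), `strictness_ah`,
#'   `strictness_bs`, `seed`. Task-specific: `algorithm`, `homogeneous`,
#'   `pack_sheets`, `hierarchical` (decompose); `template`, `db`,
#'   `ss_score`, `tt_score`, `max_rmsd`, `cluster`, `rmsd_cut` (library);
#'   `fold`, `target` (superpose); `kind`, `length`, `noise` (fixture).
#' @export
run_task <- function(task, params = list(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name, default = NULL) params[[name]] %||% default
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  files <- character(0)
  payload <- list()

  if (task == "annotate") {
    strc <- parse_structure(p("input"))
    ann <- annotate_structure(strc, p("strictness_ah", 0.5),
                              p("strictness_bs", 0.3))
    labels_json <- file.path(out_dir, "labels.json")
    jsonlite::write_json(lapply(seq_along(ann$labels), function(s) {
      list(chain = strc$stretches[[s]]$chain,
           resno = strc$stretches[[s]]$resno, label = ann$labels[[s]])
    }), labels_json, auto_unbox = TRUE, digits = NA)
    spdb <- file.path(out_dir, "strictnesses.pdb")
    write_strictness_pdb(ann, spdb)
    rep <- annotation_report(ann, out_dir)
    gml <- file.path(out_dir, "cv_graph.graphml")
    write_graphml(ann$graph, gml)
    files <- c(labels_json, spdb, attr(rep, "files"), gml)
    payload <- list(percentages = as.list(residue_percentages(ann)),
                    n_fragments = length(ann$fragments))
  } else if (task == "decompose") {
    strc <- parse_structure(p("input"))
    ann <- annotate_structure(strc, p("strictness_ah", 0.5),
                              p("strictness_bs", 0.3))
    if (isTRUE(p("hierarchical", FALSE))) {
      tree <- decompose_hierarchical(ann)
      dendro <- file.path(out_dir, "dendrogram.png")
      plot_dendrogram(tree, dendro)
      files <- c(files, dendro)
      payload$levels <- lapply(tree$levels, function(l) {
        list(groups = max(l$membership), modularity = l$modularity)
      })
      dec <- decompose_fold(ann, algorithm = p("algorithm", "fastgreedy"),
                       sheets_together = isTRUE(p("pack_sheets", FALSE)),
                       homogeneous_size = isTRUE(p("homogeneous", FALSE)),
                       seed = p("seed", 42L))
    } else {
      dec <- decompose_fold(ann, algorithm = p("algorithm", "fastgreedy"),
                       sheets_together = isTRUE(p("pack_sheets", FALSE)),
                       homogeneous_size = isTRUE(p("homogeneous", FALSE)),
                       seed = p("seed", 42L))
    }
    grouped <- file.path(out_dir, "decomposition.pdb")
    write_decomposition(ann, dec, grouped)
    gml <- file.path(out_dir, "fragment_graph.graphml")
    write_graphml(ann$fragment_graph, gml)
    files <- c(files, grouped, gml)
    payload$groups <- dec$membership
    payload$modularity <- dec$modularity
  } else if (task == "generate-library") {
    manifest <- generate_library(
      p("template"), p("db"), out_dir = out_dir,
      ss_threshold = p("ss_score", 45), tt_threshold = p("tt_score", 55),
      strictness_ah = p("strictness_ah", 0.5),
      strictness_bs = p("strictness_bs", 0.3),
      max_rmsd = p("max_rmsd", 5.0),
      sequence_pattern = p("sequence_pattern"),
      disulfide = isTRUE(p("disulfide", FALSE)),
      require_connectivity = isTRUE(p("require_connectivity", FALSE)),
      multi_chain = isTRUE(p("multi_chain", FALSE)),
      b_factor = p("b_factor", 25.0), id_list = p("id_list"))
    files <- file.path(out_dir, "library", manifest$file)
    if (!is.null(p("cluster"))) {
      cl <- cluster_library(file.path(out_dir, "library"), manifest,
                            mode = p("cluster"),
                            rmsd_cut = p("rmsd_cut", 1.0),
                            n = p("n", 10L), seed = p("seed", 42L),
                            clusters_dir = file.path(out_dir, "clusters"))
      payload$clusters <- cl
      for (k in unique(cl[!is.na(cl)])) {
        d <- file.path(out_dir, "clusters", sprintf("cluster_%d", k))
        files <- c(files, file.path(d, manifest$file[which(cl == k)]))
      }
    }
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, mpath)
    payload$n_models <- nrow(manifest)
  } else if (task == "superpose") {
    target <- parse_structure(p("target"))
    sites <- superpose_fold(p("fold"), target,
                            ss_threshold = p("ss_score", 45),
                            tt_threshold = p("tt_score", 55),
                            strictness_ah = p("strictness_ah", 0.5),
                            strictness_bs = p("strictness_bs", 0.3))
    payload$sites <- lapply(sites, function(s) {
      list(site_index = s$site_index, rmsd = s$rmsd,
           n_core = nrow(s$core),
           trims = lapply(s$trimmed, as.integer),
           rotation = s$rotation, translation = s$translation)
    })
    for (s in sites) {
      f <- file.path(out_dir, sprintf("superposed_site_%d.pdb", s$site_index))
      write_superposed(target, s, f)
      files <- c(files, f)
    }
  } else if (task == "make-fixture") {
    kind <- p("kind", "ah")
    len <- p("length", 12L)
    if (kind %in% c("ah", "bs", "coil")) {
      fx <- assemble_fold(list(element(kind, len)),
                          noise_sigma = p("noise", 0), seed = p("seed", 1L))
    } else if (kind == "sheet") {
      fx <- assemble_fold(sheet_elements(p("pattern", "UDU"), length = len),
                          noise_sigma = p("noise", 0), seed = p("seed", 1L))
    } else stop("unknown fixture kind: ", kind)
    fpdb <- file.path(out_dir, "fixture.pdb")
    write_structure(fx$structure, fpdb)
    truth <- file.path(out_dir, "fixture_truth.json")
    jsonlite::write_json(fx$truth, truth, auto_unbox = TRUE, digits = NA)
    files <- c(fpdb, truth)
    payload$elements <- nrow(fx$truth$elements)
  } else {
    stop("unknown task: ", task)
  }

  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
             "", files)
  summary <- list(task = task, parameters = params,
                  outputs = as.list(rel),
                  payload = payload,
                  started = started,
                  finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(summary)
}
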