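#' Extract one subject's record from a cohort
#'
#' @param cohort An `fc_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param subject_id Subject identifier from the manifest.
#' @return A `subject_record`: manifest fields plus `matrices`, a named list
#'   of [connectome_matrix()] objects for every modality.
#' @export
cohort_subject <- function(cohort, subject_id) {
  i <- match(subject_id, cohort$manifest$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id)
  map <- edge_index_map(n_nodes(cohort$atlas))
  mats <- lapply(setNames(names(cohort$edges), names(cohort$edges)),
                 function(mod) {
    e <- cohort$edges[[mod]]
    devectorize(structure(list(values = e$values[i, ],
                               present = e$present[i, ],
                               index_map = map, modality = mod),
                          class = "edge_vector"))
  })
  rec <- c(as.list(cohort$manifest[i, , drop = FALSE]),
           list(matrices = mats, atlas = cohort$atlas))
  rec$ravlt <- unlist(cohort$manifest[i, c("ravlt_learning", "ravlt_immediate",
                                           "ravlt_delay30",
                                           "ravlt_recognition")])
  class(rec) <- "subject_record"
  rec
}

cohort_group_rows <- function(cohort, group) {
  rows <- which(cohort$manifest$group == group)
  if (length(rows) == 0L) stop("empty group: ", group)
  rows
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort` emits `atlas.tsv`, `manifest.tsv` (demographics, cognition
#' and per-modality file paths) and one TSV connectome per subject and
#' modality; planted ground-truth parameters go to `ground_truth.json`.
#' `read_cohort` rebuilds the `fc_cohort` from such a directory.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: an `fc_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  man <- cohort$manifest
  mods <- names(cohort$edges)
  for (mod in mods)
    man[[paste0("path_", mod)]] <-
      file.path("connectomes", paste0(man$subject_id, "_", mod, ".tsv"))
  dir.create(file.path(dir, "connectomes"), showWarnings = FALSE)
  for (id in man$subject_id) {
    rec <- cohort_subject(cohort, id)
    for (mod in mods)
      write_connectome(rec$matrices[[mod]],
                       file.path(dir, "connectomes",
                                 paste0(id, "_", mod, ".tsv")),
                       labels = cohort$atlas$label)
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  if (!is.null(gt)) {
    gt$template <- NULL  # bulky; reproducible from config + seed
    gt$config <- unclass(gt$config)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  mods <- sub("^path_", "", grep("^path_", names(man), value = TRUE))
  n <- nrow(man); m <- n_edges(n_nodes(atlas))
  edges <- lapply(setNames(mods, mods), function(mod) {
    values <- matrix(NA_real_, n, m)
    present <- matrix(FALSE, n, m)
    for (i in seq_len(n)) {
      cm <- read_connectome(file.path(dir, man[[paste0("path_", mod)]][i]),
                            mod, atlas)
      ev <- vectorize(cm)
      values[i, ] <- ev$values
      present[i, ] <- ev$present
    }
    list(values = values, present = present)
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
        else NULL
  structure(list(atlas = atlas,
                 manifest = man[, !grepl("^path_", names(man))],
                 edges = edges, ground_truth = gt),
            class = "fc_cohort")
}
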