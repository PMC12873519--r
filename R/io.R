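# Accepted aliases for the canonical trait-table columns (case-insensitive).
.col_aliases <- list(
  species = c("species", "species_name", "taxon", "tip_label"),
  leaf_length_cm = c("leaf_length_cm", "leaf_length", "l", "leaf.length"),
  d_pet_um = c("d_pet_um", "d_pet", "dpet", "petiole_vessel_diameter_um"),
  d_twig_um = c("d_twig_um", "d_twig", "dtwig", "twig_vessel_diameter_um"),
  wood_density_g_cm3 = c("wood_density_g_cm3", "wood_density", "wd"),
  height_m = c("height_m", "height", "plant_height_m", "h"),
  leaf_type = c("leaf_type", "leaftype"),
  site = c("site", "locality")
)

#' Read and validate a species trait table from CSV
#'
#' Expects one row per species with leaf length (cm), petiole- and
#' twig-vessel diameters (um), wood density (g/cm3), plant height (m), and
#' optionally leaf type (simple/compound) and site. Common column aliases
#' are accepted case-insensitively and renamed (with a message). Rows with
#' missing or non-positive values in any numeric trait are flagged, dropped
#' and reported; the row-level report is attached as
#' `attr(table, "validation")`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated trait `data.frame`.
#' @export
read_trait_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(trimws(names(raw)))
  out <- list()
  for (canon in names(.col_aliases)) {
    hit <- which(nm %in% .col_aliases[[canon]])
    if (length(hit)) {
      if (nm[hit[1]] != canon)
        message("column '", names(raw)[hit[1]], "' read as '", canon, "'")
      out[[canon]] <- raw[[hit[1]]]
    }
  }
  required <- c("species", "leaf_length_cm", "d_pet_um", "d_twig_um",
                "wood_density_g_cm3", "height_m")
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("trait table at '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "),
         "\n  expected (or aliases of): ",
         paste(required, collapse = ", "), call. = FALSE)
  tab <- as.data.frame(out, stringsAsFactors = FALSE)
  num_cols <- setdiff(required, "species")
  for (cl in num_cols) tab[[cl]] <- suppressWarnings(as.numeric(tab[[cl]]))
  bad_rows <- apply(tab[num_cols], 1,
                    function(r) any(is.na(r)) || any(r <= 0))
  report <- data.frame(species = tab$species, excluded = bad_rows)
  if (any(bad_rows)) {
    message("excluding ", sum(bad_rows),
            " row(s) with missing or non-positive trait values: ",
            paste(utils::head(tab$species[bad_rows], 5), collapse = ", "),
            if (sum(bad_rows) > 5) ", ...")
    tab <- tab[!bad_rows, , drop = FALSE]
  }
  if (anyDuplicated(tab$species))
    stop("duplicate species ids: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "),
         call. = FALSE)
  rownames(tab) <- NULL
  attr(tab, "validation") <- report
  tab
}

#' Write a trait table to CSV
#' @param table Trait data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end, seeded workflow on a trait table and ultrametric tree (read
#' from files or simulated): descriptive statistics; the nine log-log
#' scaling regressions; the Welch comparison of the petiole-vs-leaf-length
#' and twig-vs-leaf-length exponents; leaf-type and site interaction models
#' on the twig~petiole relation; phylogenetic signal (Pagel's lambda,
#' Blomberg's K) for each log10 trait; PGLS under WN/BM/OU with AICc
#' ranking for every scaling relation; and the stem-vs-leaf cumulative
#' hydraulic resistance curves. Species in the table but not on the tree
#' (or vice versa) are dropped from the phylogenetic stages with a logged
#' count. If `out_dir` is given, tables are written as TSV and the whole
#' bundle as JSON (requires the jsonlite package).
#'
#' @param table_path,tree_path Paths to a trait CSV and a Newick tree.
#' @param table,tree Alternatively, in-memory objects.
#' @param simulate If `TRUE` (or a [generative_config()]), simulate both
#'   inputs instead of reading them.
#' @param seed Integer seed for every stochastic stage.
#' @param n_perm Permutations for the Blomberg K test.
#' @param alpha Fixed OU rate for the PGLS stage.
#' @param out_dir Optional output directory.
#' @return An object of class `leafxylem_report` (a named list of stages).
#' @export
run_pipeline <- function(table = NULL, tree = NULL,
                         table_path = NULL, tree_path = NULL,
                         simulate = FALSE, seed = 1L, n_perm = 199L,
                         alpha = 1, out_dir = NULL) {
  seed <- as.integer(seed)
  sim_requested <- !identical(simulate, FALSE)
  if (sim_requested &&
      (!is.null(table) || !is.null(table_path) || !is.null(tree_path)))
    stop("give either input paths/objects or simulation settings, not both",
         call. = FALSE)
  if (sim_requested) {
    cfg <- if (inherits(simulate, "generative_config")) simulate
           else generative_config(seed = seed)
    tree <- generate_tree(cfg$n_species, seed = seed)
    table <- generate_traits(cfg, tree)
  } else {
    if (is.null(table)) {
      if (is.null(table_path)) stop("no trait table given", call. = FALSE)
      table <- read_trait_table(table_path)
    }
    if (is.null(tree) && !is.null(tree_path)) tree <- read_tree(tree_path)
  }

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  report <- list(seed = seed, n_species = nrow(table))
  summ <- stage("allometry", summary_table(table))
  report$descriptives <- summ$descriptives
  report$scaling <- summ$scaling
  report$slope_comparison <- stage("slope_comparison", {
    compare_slopes(fit_loglog(table, "d_pet_um", "leaf_length_cm"),
                   fit_loglog(table, "d_twig_um", "leaf_length_cm"))
  })
  report$interactions <- stage("interactions", {
    out <- list()
    for (g in c("leaf_type", "site"))
      if (g %in% names(table) && length(unique(table[[g]])) >= 2)
        out[[g]] <- fit_with_group(table, "d_twig_um", "d_pet_um", g)
    out
  })

  if (!is.null(tree)) {
    tree <- stage("tree", {
      if (!ape::is.binary(tree)) resolve_polytomies(tree, seed = seed)
      else tree
    })
    shared <- intersect(table$species, tree$tip.label)
    if (length(shared) < nrow(table) ||
        length(shared) < length(tree$tip.label))
      message("phylogenetic stages use ", length(shared),
              " species shared by table (", nrow(table), ") and tree (",
              length(tree$tip.label), ")")
    ptab <- table[match(shared, table$species), , drop = FALSE]
    ptree <- ape::keep.tip(tree, shared)
    num_cols <- c("leaf_length_cm", "d_twig_um", "d_pet_um",
                  "wood_density_g_cm3", "height_m")
    report$phylo_signal <- stage("phylo_signal", {
      do.call(rbind, lapply(num_cols, function(cl) {
        s <- phylo_signal(stats::setNames(log10(ptab[[cl]]), ptab$species),
                          ptree, n_perm = n_perm, seed = seed)
        data.frame(trait = cl, lambda = s$lambda, lambda_p = s$lambda_p,
                   K = s$K, K_p = s$K_p)
      }))
    })
    report$pgls <- stage("pgls", {
      rel <- .standard_relations()
      do.call(rbind, lapply(seq_len(nrow(rel)), function(i)
        pgls_scaling(ptab, ptree, rel[i, 1], rel[i, 2],
                     alpha = alpha)$summary))
    })
    report$n_phylo <- length(shared)
  }

  report$hydraulics <- stage("hydraulics", {
    stem <- conduit_profile(d_ref = 10, x_ref = 1, b = 0.2)
    leaf <- conduit_profile(d_ref = 10, x_ref = 1, b = 0.4)
    data.frame(
      distance_mm = cumulative_resistance(stem, 1000)$distance_mm,
      stem_b0.2 = cumulative_resistance(stem, 1000)$cumulative_resistance,
      leaf_b0.4 = cumulative_resistance(leaf, 1000)$cumulative_resistance
    )
  })

  report <- structure(report, class = "leafxylem_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.leafxylem_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, ", ", x$n_species, " species)\n",
      sep = "")
  cat("stages:", paste(setdiff(names(x), c("seed", "n_species")),
                       collapse = ", "), "\n")
  cat("\nScaling regressions:\n")
  print(transform(x$scaling[, c("response", "predictor", "n", "adj_r2",
                                "slope", "slope_lower", "slope_upper")],
                  adj_r2 = round(adj_r2, 2), slope = round(slope, 3),
                  slope_lower = round(slope_lower, 3),
                  slope_upper = round(slope_upper, 3)))
  print(x$slope_comparison)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' TSV for every tabular stage; one JSON file for the machine-readable
#' bundle (written only if jsonlite is installed).
#'
#' @param report A `leafxylem_report`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, file)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtsv(report$descriptives, "descriptives.tsv")
  wtsv(report$scaling, "scaling_regressions.tsv")
  wtsv(report$hydraulics, "hydraulic_resistance.tsv")
  if (!is.null(report$phylo_signal)) wtsv(report$phylo_signal, "phylo_signal.tsv")
  if (!is.null(report$pgls)) wtsv(report$pgls, "pgls.tsv")
  sc <- report$slope_comparison
  wtsv(data.frame(comparison = paste(sc$labels, collapse = " vs "),
                  t = sc$t, df = sc$df, p_value = sc$p_value),
       "slope_comparison.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    keep <- !vapply(report, function(el)
      inherits(el, c("slope_comparison", "group_fit")) || is.list(el) &&
        !is.data.frame(el), logical(1))
    js <- report[keep]
    js$slope_comparison <- list(t = sc$t, df = sc$df, p_value = sc$p_value)
    if (!is.null(report$interactions))
      js$interactions <- lapply(report$interactions, function(g)
        list(group = g$group, interaction_p = g$interaction_p,
             group_p = g$group_p))
    jsonlite::write_json(js, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(out_dir)
}
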