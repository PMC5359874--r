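## End-to-end orchestration: taxon reduction to genus level, outgroup
## coding, total-evidence assembly, per-subclass parsimony analysis,
## morphology-based placement, subclass-tree grafting and ancestral-state
## reporting, with a manifest sufficient to re-run identically.

#' Reduce a dataset to one representative per genus
#'
#' Keeps exactly the species named in the retention map (chosen, in the
#' study design, to minimize missing data), relabels them to their genus
#' names, and drops all other rows.  A drop log is attached.
#'
#' @param x a [character_matrix()] or [nt_alignment()].
#' @param retention_map named character vector: names are the retained
#'   species labels, values the genus labels they become.
#' @return the reduced object, with attribute `drop_log` (character vector
#'   of dropped labels).
#' @export
reduce_taxa <- function(x, retention_map) {
  keep <- normalize_label(names(retention_map))
  genus <- normalize_label(unname(retention_map))
  if (anyDuplicated(genus))
    stop_glasstree("retention map assigns two species to genus '",
                   genus[duplicated(genus)][1], "'")
  absent <- setdiff(keep, rownames(x))
  if (length(absent) > 0)
    stop_glasstree("retained species '", absent[1], "' absent from data")
  dropped <- setdiff(rownames(x), keep)
  m <- unclass(x)[keep, , drop = FALSE]
  rownames(m) <- genus
  out <- if (inherits(x, "nt_alignment")) {
    nt_alignment(m, partitions = partitions_of(x))
  } else {
    character_matrix(m, partitions = partitions_of(x),
                     missing = missing_symbol(x),
                     character_labels = colnames(x))
  }
  attr(out, "drop_log") <- dropped
  out
}

#' Append an artificial all-zero outgroup
#'
#' Adds one taxon whose morphological characters are all coded absent
#' (`0`) -- a rooting device for matrices whose characters are not
#' comparable to any real outgroup -- and whose molecular cells (if any)
#' are missing.
#'
#' @param matrix a [character_matrix()].
#' @param label outgroup label (must be unused).
#' @param morphological_partitions names of the partitions to zero-code;
#'   default all partitions (a morphology-only matrix).
#' @return a [character_matrix()] with one extra row.
#' @export
add_artificial_outgroup <- function(matrix, label = "artificial_outgroup",
                                    morphological_partitions = NULL) {
  label <- normalize_label(label)
  if (label %in% rownames(matrix))
    stop_glasstree("label '", label, "' already present")
  parts <- partitions_of(matrix)
  if (is.null(morphological_partitions))
    morphological_partitions <- names(parts)
  unknown <- setdiff(morphological_partitions, names(parts))
  if (length(unknown) > 0)
    stop_glasstree("unknown partition '", unknown[1], "'")
  row <- rep(missing_symbol(matrix), ncol(matrix))
  for (p in morphological_partitions) row[parts[[p]]] <- "0"
  m <- rbind(unclass(matrix), row)
  rownames(m)[nrow(m)] <- label
  character_matrix(m, partitions = parts, missing = missing_symbol(matrix),
                   character_labels = colnames(matrix))
}

#' Assemble a total-evidence matrix
#'
#' Recodes the molecular alignment for parsimony (A/C/G/T to 0--3,
#' ambiguities and gaps to missing), optionally reduces both blocks to
#' genus level, and concatenates molecular + morphology under the
#' union-fill-missing policy, preserving the partition scheme.
#'
#' @param molecular an [nt_alignment()].
#' @param morphology a [character_matrix()].
#' @param retention_map optional map passed to [reduce_taxa()] (applied to
#'   both blocks where labels match).
#' @return a [character_matrix()] with attribute `summary` (the
#'   [summarize_matrix()] of the result).
#' @export
build_total_evidence <- function(molecular, morphology,
                                 retention_map = NULL) {
  if (!is.null(retention_map)) {
    sub_mol <- retention_map[normalize_label(names(retention_map)) %in%
                               rownames(molecular)]
    sub_mor <- retention_map[normalize_label(names(retention_map)) %in%
                               rownames(morphology)]
    if (length(sub_mol) > 0) molecular <- reduce_taxa(molecular, sub_mol)
    if (length(sub_mor) > 0) morphology <- reduce_taxa(morphology, sub_mor)
  }
  recoded <- recode_nucleotides(molecular)
  if (length(intersect(rownames(recoded), rownames(morphology))) == 0)
    stop_glasstree("no taxa shared between molecular and morphology blocks")
  out <- concatenate_matrices(list(molecular = recoded,
                                   morphology = morphology),
                              policy = "union")
  attr(out, "summary") <- summarize_matrix(out)
  out
}

#' Graft two subclass trees under a common root
#'
#' Each tree is expected to be rooted with a designated functional
#' outgroup leaf (a representative of the other subclass); that leaf is
#' removed and the two ingroup trees are joined as the two children of a
#' new root.
#'
#' @param tree_a,tree_b rooted phylo objects.
#' @param outgroup_a,outgroup_b the functional outgroup leaf of each tree.
#' @return a rooted phylo on the union of the ingroup leaves.
#' @export
graft_subclass_trees <- function(tree_a, tree_b, outgroup_a, outgroup_b) {
  drop1 <- function(tr, og) {
    og <- normalize_label(og)
    if (!og %in% tr$tip.label)
      stop_glasstree("outgroup '", og, "' not in tree")
    tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    ape::drop.tip(tr, og)
  }
  a <- drop1(tree_a, outgroup_a)
  b <- drop1(tree_b, outgroup_b)
  overlap <- intersect(a$tip.label, b$tip.label)
  if (length(overlap) > 0)
    stop_glasstree("overlapping leaf '", overlap[1],
                   "' in both subclass trees")
  out <- join_trees(a, b)
  out$edge.length <- NULL
  out
}

#' Workflow configuration
#'
#' @param dataset a `study_set` from [make_study_like_dataset()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; all stage seeds derive from it.
#' @param run_mp,run_bootstrap,run_placement,run_asr stage toggles.
#' @param mp_additions random-addition starts of the total-evidence
#'   searches.
#' @param mp_swap swap strategy for the total-evidence searches (`"NNI"`
#'   by default: the matrices are large and addition orders already vary).
#' @param bootstrap_replicates pseudoreplicates per subclass when
#'   bootstrapping (defaults 1000 small / 550 large, the study's settings).
#' @param asr_characters morphology character indices (of the large
#'   subclass block) reported in the ASR stage.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(dataset, out_dir, seed = 1L,
                            run_mp = TRUE, run_bootstrap = FALSE,
                            run_placement = TRUE, run_asr = TRUE,
                            mp_additions = 1L, mp_swap = "NNI",
                            bootstrap_replicates = c(small = 1000L,
                                                     large = 550L),
                            asr_characters = 1:3) {
  stopifnot(inherits(dataset, "study_set"))
  structure(list(dataset = dataset, out_dir = out_dir,
                 seed = as.integer(seed), run_mp = run_mp,
                 run_bootstrap = run_bootstrap,
                 run_placement = run_placement, run_asr = run_asr,
                 mp_additions = as.integer(mp_additions),
                 mp_swap = mp_swap,
                 bootstrap_replicates = bootstrap_replicates,
                 asr_characters = asr_characters),
            class = "workflow_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis workflow
#'
#' Executes the enabled stages in order -- functional-outgroup coding,
#' total-evidence assembly per subclass, MP search and strict consensus,
#' optional character bootstrap, morphology-based placement of taxa
#' without molecular data onto a molecular backbone, grafting of the two
#' subclass trees, and an ASR report on the combined tree -- writing every
#' artifact plus a manifest to `config$out_dir`.  Outputs are a pure
#' function of (dataset, config, seed); re-running with the same seed
#' reproduces every artifact byte for byte (the manifest records the
#' wall-clock time stamp on its first line, which is excluded from that
#' guarantee).
#'
#' @param config a [workflow_config()].
#' @return the manifest, invisibly (data.frame of artifacts + checksums).
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- config$dataset
  seed <- config$seed
  emit <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_glasstree("stage '", name, "' failed: ", conditionMessage(e)))
  }

  subclasses <- list(
    small = list(tree = ds$tree_small, morph = ds$morphology$small,
                 og_from = "large"),
    large = list(tree = ds$tree_large, morph = ds$morphology$large,
                 og_from = "small"))
  te <- list(); mp <- list()

  for (sc in names(subclasses)) {
    info <- subclasses[[sc]]
    other <- subclasses[[info$og_from]]
    og <- other$tree$tip.label[1] # functional outgroup from the other subclass
    stage(paste0("total_evidence_", sc), {
      morph <- info$morph
      # functional outgroup: all-zero morphology, as in the study design
      m <- rbind(unclass(morph),
                 setNames(rep("0", ncol(morph)), NULL))
      rownames(m)[nrow(m)] <- og
      morph_og <- character_matrix(m, missing = missing_symbol(morph))
      mol_taxa <- c(info$tree$tip.label, og)
      mol <- nt_alignment(unclass(ds$molecular)[mol_taxa, , drop = FALSE],
                          partitions = partitions_of(ds$molecular))
      te[[sc]] <- build_total_evidence(mol, morph_og)
      write_character_matrix(te[[sc]], out(paste0("total_evidence_", sc,
                                                  ".nex")))
      emit <- c(emit, paste0("total_evidence_", sc, ".nex"))
      sm <- summarize_matrix(te[[sc]])
      write_tsv(data.frame(subclass = sc, n_taxa = sm$n_taxa,
                           n_characters = sm$n_characters,
                           distinct_patterns = sm$distinct_patterns_total,
                           missing_fraction = round(sm$missing_fraction, 4)),
                out(paste0("summary_", sc, ".tsv")))
      emit <- c(emit, paste0("summary_", sc, ".tsv"))
    })
    if (config$run_mp) {
      stage(paste0("mp_", sc), {
        cfg <- search_config(n_random_additions = config$mp_additions,
                             swap_strategy = config$mp_swap,
                             seed = derive_seed(seed, 100 + match(sc,
                                                names(subclasses))),
                             keep_max = 16L)
        res <- mp_search(te[[sc]], cfg)
        mp[[sc]] <- res
        writeLines(vapply(res$trees, write_tree, character(1)),
                   out(paste0("mp_trees_", sc, ".nwk")))
        cons <- consensus_tree(res$trees, "strict")
        write_tree(cons, out(paste0("mp_strict_consensus_", sc, ".nwk")))
        stats <- fitch_length(res$trees[[1]], te[[sc]])
        write_tsv(data.frame(subclass = sc, n_trees = length(res$trees),
                             score = round(res$score, 6),
                             tree_length = stats$tree_length,
                             CI = round_half_up(stats$CI, 2),
                             RI = round_half_up(stats$RI, 2),
                             RC = round_half_up(stats$RC, 2)),
                  out(paste0("mp_stats_", sc, ".tsv")))
        emit <- c(emit, paste0("mp_trees_", sc, ".nwk"),
                   paste0("mp_strict_consensus_", sc, ".nwk"),
                   paste0("mp_stats_", sc, ".tsv"))
      })
      if (config$run_bootstrap) {
        stage(paste0("bootstrap_", sc), {
          cfg <- search_config(n_random_additions = 1L,
                               swap_strategy = config$mp_swap,
                               seed = derive_seed(seed, 200))
          bs <- bootstrap_support(te[[sc]], cfg,
                                  replicates =
                                    config$bootstrap_replicates[[sc]],
                                  seed = derive_seed(seed, 300),
                                  reference_tree = mp[[sc]]$trees[[1]])
          ape::write.tree(bs$tree, out(paste0("bootstrap_", sc, ".nwk")))
          emit <- c(emit, paste0("bootstrap_", sc, ".nwk"))
        })
      }
    }
  }

  if (config$run_placement) {
    stage("placement", {
      seqd <- ds$sequenced_taxa
      mol_seq <- nt_alignment(unclass(ds$molecular)[seqd, , drop = FALSE],
                              partitions = partitions_of(ds$molecular))
      recoded <- recode_nucleotides(mol_seq)
      cfg <- search_config(n_random_additions = 1L, swap_strategy = "NNI",
                           seed = derive_seed(seed, 400), keep_max = 1L)
      backbone <- mp_search(recoded, cfg)$trees[[1]]
      morph_all <- concatenate_matrices(
        list(small = ds$morphology$small, large = ds$morphology$large),
        policy = "union")
      w <- calibrate_weights(backbone, morph_all)
      queries <- setdiff(rownames(morph_all), backbone$tip.label)
      pl <- place_all(backbone, w, morph_all, queries)
      write_tree(pl$composite_tree, out("placement_composite.nwk"))
      write_tsv(data.frame(
        query = names(pl$placements),
        best_edge = vapply(pl$placements, `[[`, 0L, "best_edge"),
        score = round(vapply(pl$placements, function(p)
          p$ranking$score[1], numeric(1)), 6),
        tie = vapply(pl$placements, `[[`, FALSE, "tie")),
        out("placement_results.tsv"))
      emit <- c(emit, "placement_composite.nwk", "placement_results.tsv")
    })
  }

  combined <- NULL
  if (config$run_mp) {
    stage("graft", {
      # each subclass tree was searched with its functional outgroup in
      combined <- graft_subclass_trees(
        mp$small$trees[[1]], mp$large$trees[[1]],
        subclasses$large$tree$tip.label[1],
        subclasses$small$tree$tip.label[1])
      write_tree(combined, out("combined_tree.nwk"))
      emit <- c(emit, "combined_tree.nwk")
    })
  }

  if (config$run_asr && !is.null(combined)) {
    stage("asr", {
      morph_all <- concatenate_matrices(
        list(small = ds$morphology$small, large = ds$morphology$large),
        policy = "union")
      queries <- list(
        root = combined$tip.label,
        small_lca = intersect(ds$tree_small$tip.label,
                              combined$tip.label),
        large_lca = intersect(ds$tree_large$tip.label,
                              combined$tip.label))
      # characters indexed within the large block of the concatenation
      chars <- ncol(ds$morphology$small) + config$asr_characters
      rep <- asr_report(combined, morph_all, chars, queries,
                        seed = derive_seed(seed, 500))
      write_tsv(rep, out("asr_report.tsv"))
      emit <- c(emit, "asr_report.tsv")
    })
  }

  manifest <- data.frame(
    file = emit,
    md5 = unname(tools::md5sum(file.path(config$out_dir, emit))))
  hdr <- c(paste0("# generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           paste0("# glasstree version: ",
                  as.character(packageVersion("glasstree"))),
           paste0("# seed: ", seed),
           paste0("# stages: mp=", config$run_mp,
                  " bootstrap=", config$run_bootstrap,
                  " placement=", config$run_placement,
                  " asr=", config$run_asr))
  writeLines(c(hdr, paste(manifest$file, manifest$md5, sep = "\t")),
             out("MANIFEST.txt"))
  invisible(manifest)
}
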