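#' Run the full ligand-transference pipeline on a structure directory
#'
#' Executes the stages in order: parse every `.pdb`/`.cif` file in
#' `input_dir`; extract contacting chain-ligand complexes; annotate solvent
#' and promiscuity flags; build the bipartite network; enumerate candidate
#' triplets (identity, Tanimoto and atom-ratio filters); build each
#' predicted complex (per-candidate failures are logged and skipped);
#' reject predictions with severe steric clashes (same rule as decoy
#' filtering); score survivors against the decoy reference; report.
#'
#' @param input_dir directory of structure files.
#' @param reference a [score_reference], a path to a serialized reference,
#'   or `NULL` to generate one from the extracted complexes (`n_decoys`,
#'   `seed`).
#' @param n_decoys decoys to generate when no reference is supplied
#'   (default 200; at least 100 are required to build a reference).
#' @param seed integer seed for decoy generation.
#' @param config a [scoring_config]; `p_cutoff` sets the significance line.
#' @param out_report optional path for the TSV report (sorted by p then by
#'   descending S; deterministic for a fixed seed and input).
#' @param quiet suppress stage messages.
#' @return object of class `ligtrans_run`: `report` (tibble, one row per
#'   scored prediction), `summary` (stage counts), `predictions` (list of
#'   [predicted_complex]), `reference`, `config`.
#' @export
run_pipeline <- function(input_dir, reference = NULL, n_decoys = 200,
                         seed = 1, config = scoring_config(),
                         out_report = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- list.files(input_dir, pattern = "\\.(pdb|ent|cif)$",
                      full.names = TRUE, ignore.case = TRUE)
  files <- files[order(basename(files))]
  # one dialect per structure: skip the .cif duplicate when the same stem
  # exists as .pdb
  stem <- sub("\\.[^.]+$", "", basename(files))
  files <- files[!duplicated(stem)]

  complexes <- list()
  for (f in files) {
    parsed <- tryCatch(parse_structure(f,
                         min_heavy_atoms = config$min_heavy_atoms),
                       error = function(e) { say("skip %s: %s", basename(f),
                                                 conditionMessage(e)); NULL })
    if (is.null(parsed)) next
    complexes <- c(complexes,
                   extract_complexes(parsed$chains, parsed$ligands,
                                     cutoff = config$contact_cutoff))
  }
  complexes <- flag_ligands(complexes,
                            promiscuity_threshold = config$promiscuity_threshold)
  say("extract: %d structures, %d complexes", length(files), length(complexes))

  empty_report <- tibble(
    p1 = character(), p2 = character(), la = character(), lb = character(),
    identity = double(), tanimoto = double(), atom_ratio = double(),
    labels = character(),
    a_clash_volume = double(), b_contacts = integer(), c_hbonds = integer(),
    d_vdw_contacts = integer(), e_unsatisfied_polar = integer(),
    f_uncontacted_carbons = integer(), g_exposed_polar = integer(),
    s_a = double(), s_b = double(), s_c = double(), s_d = double(),
    s_e = double(), s_f = double(), s_g = double(),
    S = double(), p = double()
  )
  summarize_run <- function(n_cand, n_built, n_clash, n_scored, n_sig) {
    tibble(stage = c("candidates", "built", "clash_rejected", "scored",
                     "significant"),
           count = c(n_cand, n_built, n_clash, n_scored, n_sig))
  }
  finish <- function(report, summary, predictions, ref) {
    if (!is.null(out_report)) {
      utils::write.table(report, out_report, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    structure(list(report = report, summary = summary,
                   predictions = predictions, reference = ref,
                   config = config, seed = seed),
              class = "ligtrans_run")
  }
  if (length(complexes) == 0) {
    say("no complexes; empty report")
    return(finish(empty_report, summarize_run(0, 0, 0, 0, 0), list(), NULL))
  }

  net <- build_network(complexes)
  trips <- enumerate_triplets(net)
  tab <- triplet_table(trips)
  say("network: %d protein nodes, %d chemical nodes; %d candidates",
      nrow(net$proteins), nrow(net$chemicals), length(trips))
  if (length(trips) == 0) {
    return(finish(empty_report, summarize_run(0, 0, 0, 0, 0), list(), NULL))
  }

  preds <- vector("list", length(trips))
  built <- logical(length(trips))
  clash_ok <- logical(length(trips))
  for (i in seq_along(trips)) {
    pr <- tryCatch(build_prediction(trips[[i]],
                                    min_ca_pairs = config$min_ca_pairs),
                   error = function(e) { say("build failed [%d]: %s", i,
                                             conditionMessage(e)); NULL })
    if (is.null(pr)) next
    built[i] <- TRUE
    preds[[i]] <- pr
    pseudo <- structure(list(protein = pr$protein, ligand = pr$ligand),
                        class = "plc")
    clash_ok[i] <- !has_severe_clash(pseudo, config$severe_clash_factor)
  }
  say("build: %d built, %d survive severe-clash rejection",
      sum(built), sum(clash_ok))

  ref <- reference
  if (is.character(ref)) ref <- read_reference(ref)
  if (is.null(ref)) {
    decoys <- withCallingHandlers(
      generate_negatives(complexes, n_decoys, seed = seed, config = config),
      warning = function(w) { say("negatives: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    ref <- tryCatch(build_reference(decoys, config = config, seed = seed),
                    error = function(e) { say("reference: %s",
                                              conditionMessage(e)); NULL })
  }

  rows <- list()
  for (i in which(built & clash_ok)) {
    pr <- preds[[i]]
    dv <- descriptor_vector(pr$protein, pr$ligand, config)
    if (!is.null(ref)) {
      sc <- p_value(combined_score(dv, ref), ref)
      s <- sc$s; S <- sc$S; p <- sc$p
    } else {
      s <- rep(NA_real_, 7); S <- NA_real_; p <- NA_real_
    }
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tab[i, c("p1", "p2", "la", "lb", "identity", "tanimoto", "atom_ratio")],
      tibble(labels = paste(classify_prediction(trips[[i]]), collapse = ",")),
      dv[descriptor_names()],
      tibble(s_a = s[1], s_b = s[2], s_c = s[3], s_d = s[4], s_e = s[5],
             s_f = s[6], s_g = s[7], S = S, p = p)
    )
  }
  report <- if (length(rows) > 0) bind_rows(rows) else empty_report
  report <- report %>% arrange(.data$p, dplyr::desc(.data$S))
  n_sig <- sum(!is.na(report$p) & report$p <= config$p_cutoff)
  say("score: %d scored, %d significant at p <= %g",
      nrow(report), n_sig, config$p_cutoff)
  finish(report,
         summarize_run(length(trips), sum(built), sum(built & !clash_ok),
                       nrow(report), n_sig),
         preds[built & clash_ok], ref)
}

#' @export
print.ligtrans_run <- function(x, ...) {
  cat("<ligtrans_run>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
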