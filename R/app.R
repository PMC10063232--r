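# Command-line driver.  The installed script inst/cli/protfun.R is a thin
# wrapper around run_cli(); every subcommand routes its randomness through a
# single --seed and writes a JSON run manifest next to its outputs so that a
# run can be re-executed and checked (same input checksums => same outputs
# for deterministic subcommands).

cli_usage <- function() {
  paste(
    "usage: protfun.R <command> [--flag value ...]",
    "",
    "commands:",
    "  ontology-validate --edges F [--namespace synthetic|EC-like|GO-like]",
    "  synth             --out DIR --levels N --branching B[,B2,...] --n N [--seed S]",
    "                    [--lengths MIN,MAX] [--bifunctional F] [--nonenzyme F]",
    "                    [--mutation MU] [--motif-length M]",
    "  split             --out F --fasta F --labels F --edges F [--seed S]",
    "                    [--mode random|clustered] [--fractions A,B,C] [--clusters F]",
    "  stats             --fasta F --labels F --edges F --split F",
    "  train             --out CKPT --fasta F --labels F --edges F --steps N [--seed S]",
    "                    [--split F] [--filters K] [--layers K] [--token-budget T]",
    "                    [--lr X] [--warmup N] [--norm layer|none]",
    "  predict           --out F --model CKPT --fasta F [--threshold T]",
    "  eval              --pred F --labels F --edges F [--fasta F] [--bootstrap N] [--seed S]",
    "  blast-baseline    --out F --train-fasta F --train-labels F --edges F --query F",
    "                    [--backend builtin|blastp]",
    "  combine           --out F --blast F --cnn F [--union]",
    "  cam               --out F --model CKPT --fasta F --classes A,B[,...]",
    "  order-domains     --out F --model CKPT --fasta F --edges F [--threshold T]",
    "  embed             --out F --model CKPT --fasta F",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (key == "union") { flags[[key]] <- TRUE; i <- i + 1L; next }
    if (i == length(argv)) stop("flag --", key, " needs a value")
    flags[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  # a YAML config supplies defaults; explicit flags win
  if (!is.null(flags$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("--config requires the yaml package")
    cfg <- yaml::read_yaml(flags$config)
    for (k in names(cfg)) if (is.null(flags[[k]])) flags[[k]] <- cfg[[k]]
  }
  flags
}

flag_or <- function(flags, key, default = NULL) {
  if (!is.null(flags[[key]])) flags[[key]] else default
}

need_flag <- function(flags, key) {
  v <- flags[[key]]
  if (is.null(v)) stop("missing required flag --", key)
  v
}

num_list <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

write_manifest <- function(out, command, flags, inputs = character(0)) {
  dir <- if (dir.exists(out)) out else dirname(out)
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    flags = flags,
    seed = as.integer(flag_or(flags, "seed", 1L)),
    inputs = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("protfun")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(dir, paste0("manifest-", command, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

read_cli_corpus <- function(flags, fasta_key = "fasta", labels_key = "labels") {
  graph <- parse_ontology(need_flag(flags, "edges"),
                          flag_or(flags, "namespace", "synthetic"))
  corpus <- read_corpus(need_flag(flags, fasta_key),
                        need_flag(flags, labels_key), graph)
  list(graph = graph, corpus = corpus)
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the installed `protfun.R` script (see
#' `system.file("cli", "protfun.R", package = "protfun")`).  Machine-readable
#' results go to the `--out` file or directory; logs go to stderr.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status, invisibly (0 on success; 2 on a usage error).
#' @export
run_cli <- function(argv) {
  if (length(argv) == 0L || argv[1L] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(argv)) 0L else 2L))
  }
  command <- argv[1L]
  flags <- parse_cli_args(argv[-1L])
  seed <- as.integer(flag_or(flags, "seed", 1L))
  handler <- switch(
    command,
    "ontology-validate" = function() {
      g <- parse_ontology(need_flag(flags, "edges"),
                          flag_or(flags, "namespace", "synthetic"))
      message(sprintf("ok: %d labels, %d edges, acyclic", length(g$labels),
                      nrow(g$edges)))
    },
    "synth" = function() {
      out <- need_flag(flags, "out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      graph <- make_ontology(as.integer(need_flag(flags, "levels")),
                             as.integer(num_list(need_flag(flags, "branching"))))
      syn <- make_corpus(
        graph, n = as.integer(need_flag(flags, "n")),
        length_range = as.integer(num_list(flag_or(flags, "lengths", "100,600"))),
        bifunctional_fraction = as.numeric(flag_or(flags, "bifunctional", 0.1)),
        nonenzyme_fraction = as.numeric(flag_or(flags, "nonenzyme", 0.1)),
        mutation_rate = as.numeric(flag_or(flags, "mutation", 0.05)),
        motif_length = as.integer(flag_or(flags, "motif-length", 12L)),
        seed = seed)
      write_fasta(stats::setNames(syn$corpus$sequence, syn$corpus$accession),
                  file.path(out, "corpus.fasta"))
      write_label_table(syn$corpus, file.path(out, "labels.tsv"))
      write_ontology(graph, file.path(out, "ontology.tsv"))
      write_truth(syn$truth, file.path(out, "truth.tsv"))
      utils::write.table(syn$motifs, file.path(out, "motifs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      write_manifest(out, command, flags)
      message("wrote synthetic corpus to ", out)
    },
    "split" = function() {
      out <- need_flag(flags, "out")
      cc <- read_cli_corpus(flags)
      mode <- flag_or(flags, "mode", "random")
      sp <- if (mode == "clustered") {
        clustered_split(cc$corpus, need_flag(flags, "clusters"), seed)
      } else {
        random_split(cc$corpus,
                     num_list(flag_or(flags, "fractions", "0.8,0.1,0.1")), seed)
      }
      write_split(sp, out)
      write_manifest(out, command, flags,
                     c(flags$fasta, flags$labels, flags$edges))
    },
    "stats" = function() {
      cc <- read_cli_corpus(flags)
      sp <- read_split(need_flag(flags, "split"))
      print(split_stats(sp, cc$corpus))
    },
    "train" = function() {
      out <- need_flag(flags, "out")
      cc <- read_cli_corpus(flags)
      corpus <- cc$corpus
      if (!is.null(flags$split))
        corpus <- corpus_fold(corpus, read_split(flags$split), "train")
      cfg <- model_config(
        vocabulary = cc$graph$labels,
        filters = as.integer(flag_or(flags, "filters", 64L)),
        num_res_layers = as.integer(flag_or(flags, "layers", 2L)),
        norm = flag_or(flags, "norm", "layer"))
      tcfg <- train_config(
        train_steps = as.integer(need_flag(flags, "steps")),
        learning_rate = as.numeric(flag_or(flags, "lr", 1.5e-3)),
        warmup_steps = as.integer(flag_or(flags, "warmup", 3000L)),
        token_budget = as.integer(flag_or(flags, "token-budget", 2048L)),
        seed = seed)
      fit <- train_model(build_model(cfg, seed), corpus, tcfg,
                         checkpoint_path = out, verbose = TRUE)
      write_manifest(out, command, flags,
                     c(flags$fasta, flags$labels, flags$edges))
      message(sprintf("final training loss %.4f",
                      mean(utils::tail(fit$log$loss, 50L))))
    },
    "predict" = function() {
      out <- need_flag(flags, "out")
      model <- load_model(need_flag(flags, "model"))
      seqs <- read_fasta(need_flag(flags, "fasta"))
      pred <- prediction_set(model, stats::setNames(seqs, names(seqs)))
      thr <- as.numeric(flag_or(flags, "threshold", 0))
      write_predictions(pred[pred$score >= thr, ], out)
      write_manifest(out, command, flags, c(flags$model, flags$fasta))
    },
    "eval" = function() {
      pred <- read_predictions(need_flag(flags, "pred"))
      graph <- parse_ontology(need_flag(flags, "edges"),
                              flag_or(flags, "namespace", "synthetic"))
      lab <- read_label_table(need_flag(flags, "labels"))
      truth <- data.frame(
        accession = rep(lab$accession, lengths(lab$leaf_labels)),
        label = unlist(lab$leaf_labels), stringsAsFactors = FALSE)
      truth <- unique(do.call(rbind, lapply(split(truth, truth$accession),
        function(d) data.frame(accession = d$accession[1L],
                               label = propagate(graph, d$label)))))
      res <- fmax_score(pred, truth)
      reps <- as.integer(flag_or(flags, "bootstrap", 0L))
      if (reps > 0L)
        res$ci <- bootstrap_ci(pred, truth, reps = reps, seed = seed)
      cat(jsonlite::toJSON(list(fmax = res$fmax, threshold = res$threshold,
                                precision = res$precision, recall = res$recall,
                                ci = res$ci),
                           auto_unbox = TRUE, digits = NA, null = "null"), "\n")
    },
    "blast-baseline" = function() {
      out <- need_flag(flags, "out")
      cc <- read_cli_corpus(flags, "train-fasta", "train-labels")
      queries <- read_fasta(need_flag(flags, "query"))
      pred <- align_baseline(queries, cc$corpus,
                             backend = flag_or(flags, "backend", "builtin"))
      write_predictions(pred, out)
      write_manifest(out, command, flags,
                     c(flags[["train-fasta"]], flags[["train-labels"]],
                       flags$edges, flags$query))
    },
    "combine" = function() {
      out <- need_flag(flags, "out")
      pred <- combine_predictions(read_predictions(need_flag(flags, "blast")),
                                  read_predictions(need_flag(flags, "cnn")),
                                  union = isTRUE(flags$union))
      write_predictions(pred, out)
      write_manifest(out, command, flags, c(flags$blast, flags$cnn))
    },
    "cam" = function() {
      out <- need_flag(flags, "out")
      model <- load_model(need_flag(flags, "model"))
      seqs <- read_fasta(need_flag(flags, "fasta"))
      classes <- strsplit(need_flag(flags, "classes"), ",", fixed = TRUE)[[1]]
      rows <- lapply(names(seqs), function(acc) {
        m <- cam(model, seqs[[acc]], classes)
        nm <- if (length(classes) >= 2L) normalize_cam(m)$scores else m$scores * NA
        data.frame(accession = acc,
                   position = rep(seq_len(nrow(m$scores)) - 1L, length(classes)),
                   label = rep(classes, each = nrow(m$scores)),
                   raw = as.vector(m$scores), normalized = as.vector(nm))
      })
      utils::write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_manifest(out, command, flags, c(flags$model, flags$fasta))
    },
    "order-domains" = function() {
      out <- need_flag(flags, "out")
      model <- load_model(need_flag(flags, "model"))
      graph <- parse_ontology(need_flag(flags, "edges"),
                              flag_or(flags, "namespace", "synthetic"))
      seqs <- read_fasta(need_flag(flags, "fasta"))
      thr <- as.numeric(flag_or(flags, "threshold", 0.5))
      rows <- lapply(names(seqs), function(acc) {
        od <- tryCatch(order_domains(model, seqs[[acc]], graph_leaves(graph),
                                     threshold = thr),
                       error = function(e) NULL)
        if (is.null(od)) return(NULL)
        data.frame(accession = acc, first = od$order[1L], second = od$order[2L],
                   com_first = od$com[od$order[1L]],
                   com_second = od$com[od$order[2L]])
      })
      utils::write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_manifest(out, command, flags, c(flags$model, flags$fasta))
    },
    "embed" = function() {
      out <- need_flag(flags, "out")
      model <- load_model(need_flag(flags, "model"))
      seqs <- read_fasta(need_flag(flags, "fasta"))
      E <- embed(model, stats::setNames(seqs, names(seqs)))
      utils::write.table(data.frame(accession = rownames(E), E), out,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      write_manifest(out, command, flags, c(flags$model, flags$fasta))
    },
    NULL)
  if (is.null(handler)) {
    message("unknown command: ", command)
    message(cli_usage())
    return(invisible(2L))
  }
  handler()
  invisible(0L)
}
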