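#' Study configuration
#'
#' One validated object drives the whole pipeline: cohort generation,
#' preprocessing, spectral and connectivity estimation, tree construction
#' and statistics. All randomness flows from the single `seed`. A
#' configuration can also be read from a YAML file with the same field
#' names (see the package README for the documented schema).
#'
#' @param protocol `"mst_protocol"`.
#' @param coupling Named list: one `"mst_coupling"` per session label.
#' @param noise `"mst_noise"` (its seed is overridden by `seed`).
#' @param montage `"mst_montage"`.
#' @param preprocess Named list of [preprocess_recording()] parameters
#'   (low, high, bp_order, notch_freq, notch_order, factor, decay, eps,
#'   window_s); missing entries take that function's defaults.
#' @param band `"mst_band"` analyzed for connectivity (default alpha).
#' @param analyses Named list of logical toggles: `spectral`,
#'   `connectivity`, `network`, `nbs`, `metric_tests`,
#'   `write_recordings`.
#' @param nbs Named list: `t_threshold`, `n_perm`, `statistic` ("extent"
#'   or "intensity"; intensity suits strong but spatially sparse effects,
#'   where a component of one or two edges can never be an extreme edge
#'   count under the null).
#' @param out_dir Output directory.
#' @param seed Master seed (integer).
#' @return Object of class `"mst_config"`.
#' @export
study_config <- function(protocol = protocol_config(),
                         coupling = NULL,
                         noise = noise_model(),
                         montage = default_montage(),
                         preprocess = list(),
                         band = alpha_band(),
                         analyses = list(),
                         nbs = list(t_threshold = 2, n_perm = 5000,
                                    statistic = "extent"),
                         out_dir = "mstnet-results",
                         seed = 1L) {
  if (is.null(coupling)) {
    coupling <- stats::setNames(
      replicate(length(protocol$sessions), coupling_spec(), simplify = FALSE),
      protocol$sessions
    )
  }
  missing <- setdiff(protocol$sessions, names(coupling))
  if (length(missing)) {
    stop("coupling lacks sessions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cp in coupling) {
    bad <- setdiff(unique(c(cp$entries$a, cp$entries$b)), montage$labels)
    if (length(bad)) {
      stop("coupling references channels not in the montage: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  an <- utils::modifyList(
    list(spectral = TRUE, connectivity = TRUE, network = TRUE, nbs = TRUE,
         metric_tests = TRUE, write_recordings = FALSE),
    analyses
  )
  nb <- utils::modifyList(
    list(t_threshold = 2, n_perm = 5000, statistic = "extent"), nbs)
  structure(
    list(protocol = protocol, coupling = coupling, noise = noise,
         montage = montage, preprocess = preprocess, band = band,
         analyses = an, nbs = nb, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "mst_config"
  )
}

#' @rdname study_config
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  protocol <- do.call(protocol_config, y$protocol %||% list())
  montage <- if (is.null(y$montage)) {
    default_montage()
  } else {
    montage_spec(y$montage$labels, y$montage$region_map)
  }
  coupling <- NULL
  if (!is.null(y$coupling)) {
    coupling <- lapply(y$coupling, function(entries) {
      coupling_spec(do.call(rbind, lapply(entries, as.data.frame)))
    })
  }
  noise <- do.call(noise_model, y$noise %||% list())
  band <- if (is.null(y$band)) {
    alpha_band()
  } else {
    band_spec(y$band$name, y$band$low, y$band$high)
  }
  study_config(
    protocol = protocol, coupling = coupling, noise = noise,
    montage = montage, preprocess = y$preprocess %||% list(),
    band = band, analyses = y$analyses %||% list(),
    nbs = y$nbs %||% list(),
    out_dir = y$out_dir %||% "mstnet-results",
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a recording from disk
#'
#' Reads the package's plain-text array container and normalizes channel
#' order to the montage, erroring on missing channels.
#'
#' @param stem Path stem of a recording written by [write_recording()].
#' @param montage Optional `"mst_montage"` for channel normalization.
#' @return `"eeg_recording"`.
#' @export
load_recording <- function(stem, montage = NULL) {
  read_recording(stem, montage)
}

preprocess_with <- function(rec, params, meta) {
  do.call(preprocess_recording, c(list(rec = rec, meta = meta), params))
}

# concatenate epoch sets along the trial axis
bind_epochs <- function(eps) {
  if (length(eps) == 1) return(eps[[1]])
  dat <- do.call(abind3, lapply(eps, `[[`, "data"))
  epoch_set(dat, eps[[1]]$rate, eps[[1]]$labels,
            unlist(lapply(eps, `[[`, "conditions")), eps[[1]]$meta)
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    out[(at + 1):(at + k), , ] <- a
    at <- at + k
  }
  out
}

#' Run the full study pipeline
#'
#' For every group x subject x session: generates the run recordings,
#' preprocesses and epochs them, and (as enabled) computes event and
#' baseline multitaper spectra with band power, frontal alpha asymmetry
#' and relative power; the band WPLI connectivity matrix (runs pooled);
#' and the maximum-weight spanning tree with node and tree metrics. Then
#' compares sessions per group: group-averaged trees, paired NBS on the
#' connectivity stacks, edit-distance summaries, and Wilcoxon signed-rank
#' tests with FDR correction over each metric family. All intermediate
#' artifacts and result tables are written under `config$out_dir`, along
#' with a JSON run log recording the config hash, seed and stage timings.
#'
#' @param config `"mst_config"`.
#' @param quiet Suppress progress messages (default TRUE).
#' @return Object of class `"mst_results"`: `faa`, `relative_power`,
#'   `node_metrics`, `tree_metrics` (data frames), `connectivity` and
#'   `trees` (named lists by subject/session), `group_trees`, `nbs`,
#'   `ged`, `tests`, `log`.
#' @export
run_study <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "mst_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(...)
  pr <- config$protocol
  noise <- config$noise
  noise$seed <- config$seed
  out <- config$out_dir
  for (d in c("", "connectivity", "trees", "spectra", "tables",
              if (config$analyses$write_recordings) "recordings")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  window_s <- config$preprocess$window_s %||% 2
  base_win <- min(window_s, pr$inter_trial_s)

  faa_rows <- list(); rp_rows <- list(); node_rows <- list()
  tree_rows <- list()
  conns <- list(); trees <- list()
  subjects <- character(0)
  si_global <- 0L

  for (gi in seq_along(pr$groups)) {
    for (sj in seq_len(pr$subjects_per_group)) {
      subject <- sprintf("%s%02d", pr$groups[gi], sj)
      subjects <- c(subjects, subject)
      say("subject ", subject)
      subj <- generate_subject(config$montage, pr, config$coupling, noise,
                               gi, sj, config$seed)
      for (sess in pr$sessions) {
        key <- paste(subject, sess, sep = ".")
        meta <- list(subject = subject, group = pr$groups[gi],
                     session = sess)
        eps <- list(); base_eps <- list()
        for (r in seq_along(subj[[sess]])) {
          rec <- subj[[sess]][[r]]
          if (config$analyses$write_recordings) {
            write_recording(rec, file.path(out, "recordings",
                                           sprintf("%s_run%d", key, r)))
          }
          pre <- config$preprocess
          pre$window_s <- NULL
          filt <- do.call(preprocess_stages, c(list(rec = rec), pre))
          eps[[r]] <- epoch_recording(filt, window_s, meta = meta)
          base_eps[[r]] <- epoch_recording(filt, base_win,
                                           offset_s = -base_win,
                                           meta = meta)
        }
        ep <- bind_epochs(eps)
        bep <- bind_epochs(base_eps)
        if (config$analyses$spectral) {
          spec <- multitaper_psd(ep)
          bspec <- multitaper_psd(bep)
          utils::write.table(
            spec$psd, file.path(out, "spectra", paste0(key, ".tsv")),
            sep = "\t", quote = FALSE, col.names = spec$freqs
          )
          faa_rows[[key]] <- data.frame(
            subject = subject, group = pr$groups[gi], session = sess,
            faa = faa(spec, band = config$band)
          )
          rp <- relative_power(spec, bspec, config$band)
          rp_rows[[key]] <- data.frame(
            subject = subject, group = pr$groups[gi], session = sess,
            channel = names(rp), rp = unname(rp)
          )
        }
        if (config$analyses$connectivity) {
          cm <- connectivity_matrix(ep, config$band)
          conns[[key]] <- cm
          write_connectivity(cm, file.path(out, "connectivity",
                                           paste0(key, ".tsv")))
          if (config$analyses$network) {
            tr <- mst(cm)
            trees[[key]] <- tr
            write_tree(tr, file.path(out, "trees", key))
            nm <- node_metrics(tr)
            node_rows[[key]] <- cbind(
              data.frame(subject = subject, group = pr$groups[gi],
                         session = sess),
              nm
            )
            tree_rows[[key]] <- cbind(
              data.frame(subject = subject, group = pr$groups[gi],
                         session = sess),
              tree_metrics(tr)
            )
          }
        }
      }
      si_global <- si_global + 1L
    }
  }

  results <- structure(
    list(faa = rbindl(faa_rows), relative_power = rbindl(rp_rows),
         node_metrics = rbindl(node_rows), tree_metrics = rbindl(tree_rows),
         connectivity = conns, trees = trees,
         group_trees = list(), nbs = list(), ged = list(), tests = NULL),
    class = "mst_results"
  )

  if (config$analyses$network && length(trees)) {
    for (g in pr$groups) {
      for (sess in pr$sessions) {
        keys <- paste(grep(paste0("^", g), subjects, value = TRUE), sess,
                      sep = ".")
        keys <- intersect(keys, names(conns))
        if (length(keys)) {
          gt <- group_network(conns[keys])
          results$group_trees[[paste(g, sess, sep = ".")]] <- gt
          write_tree(gt, file.path(out, "trees",
                                   paste0("group_", g, "_", sess)))
        }
      }
    }
    if (length(pr$sessions) >= 2) {
      s1 <- pr$sessions[1]; s2 <- pr$sessions[2]
      for (g in pr$groups) {
        subs <- grep(paste0("^", g), subjects, value = TRUE)
        t1 <- trees[paste(subs, s1, sep = ".")]
        t2 <- trees[paste(subs, s2, sep = ".")]
        results$ged[[g]] <- list(
          between_sessions = pairwise_ged_summary(
            t1, "between_sessions", t2),
          within_session = lapply(
            stats::setNames(pr$sessions, pr$sessions),
            function(s) pairwise_ged_summary(
              trees[paste(subs, s, sep = ".")], "within_session")
          )
        )
      }
    }
  }

  if (config$analyses$nbs && length(conns) && length(pr$sessions) >= 2) {
    s1 <- pr$sessions[1]; s2 <- pr$sessions[2]
    for (gi in seq_along(pr$groups)) {
      g <- pr$groups[gi]
      subs <- grep(paste0("^", g), subjects, value = TRUE)
      if (length(subs) >= 2) {
        results$nbs[[g]] <- nbs(
          conns[paste(subs, s2, sep = ".")],
          conns[paste(subs, s1, sep = ".")],
          t_threshold = config$nbs$t_threshold,
          n_perm = config$nbs$n_perm,
          statistic = config$nbs$statistic,
          seed = derive_seed(config$seed, 7L, gi)
        )
      }
    }
    nbs_tab <- rbindl(lapply(names(results$nbs), function(g) {
      r <- results$nbs[[g]]
      if (!length(r$components)) return(NULL)
      rbindl(lapply(seq_along(r$components), function(i) {
        cbind(data.frame(group = g, component = i, p = r$p[i]),
              r$components[[i]])
      }))
    }))
    if (!is.null(nbs_tab)) {
      utils::write.table(nbs_tab,
                         file.path(out, "tables", "nbs_components.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (config$analyses$metric_tests && length(pr$sessions) >= 2) {
    results$tests <- metric_session_tests(results, pr)
    if (!is.null(results$tests)) {
      utils::write.table(results$tests,
                         file.path(out, "tables", "metric_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  for (nm in c("faa", "relative_power", "node_metrics", "tree_metrics")) {
    if (!is.null(results[[nm]])) {
      utils::write.table(results[[nm]],
                         file.path(out, "tables", paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  results$log <- list(
    config_hash = cfg_hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("mstnet")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    subjects = subjects
  )
  jsonlite::write_json(results$log, file.path(out, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  results
}

# preprocessing chain without the epoching step (runs need two different
# epoch windows: event and pre-onset baseline)
preprocess_stages <- function(rec, low = 0.5, high = 30, bp_order = 8,
                              notch_freq = 50, notch_order = 4,
                              factor = 4, decay = 0.999, eps = 1e-4) {
  rec <- bandpass_filter(rec, low, high, bp_order)
  if (!is.null(notch_freq)) rec <- notch_filter(rec, notch_freq, notch_order)
  rec <- resample_recording(rec, factor)
  ems_standardize(rec, decay, eps)
}

rbindl <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# paired pre-vs-feedback Wilcoxon tests with FDR within each metric family
metric_session_tests <- function(results, pr) {
  s1 <- pr$sessions[1]; s2 <- pr$sessions[2]
  rows <- list()
  add_family <- function(df, metric_col, unit_col, family, group) {
    units <- unique(df[[unit_col]])
    fam_rows <- lapply(units, function(u) {
      sub <- df[df[[unit_col]] == u & df$group == group, ]
      w1 <- sub[sub$session == s1, ]
      w2 <- sub[sub$session == s2, ]
      w2 <- w2[match(w1$subject, w2$subject), ]
      if (nrow(w1) < 2) return(NULL)
      p <- tryCatch(
        wilcoxon_signed_rank(w2[[metric_col]], w1[[metric_col]])$p.value,
        error = function(e) NA_real_
      )
      data.frame(group = group, family = family, unit = as.character(u),
                 p = p)
    })
    rbindl(fam_rows)
  }
  for (g in pr$groups) {
    if (!is.null(results$faa)) {
      df <- results$faa; df$unit <- "FAA"
      rows[[paste(g, "faa")]] <- add_family(df, "faa", "unit", "faa", g)
    }
    if (!is.null(results$relative_power)) {
      rows[[paste(g, "rp")]] <- add_family(results$relative_power, "rp",
                                           "channel", "relative_power", g)
    }
    if (!is.null(results$node_metrics)) {
      rows[[paste(g, "deg")]] <- add_family(results$node_metrics, "degree",
                                            "node", "degree", g)
      rows[[paste(g, "btw")]] <- add_family(results$node_metrics,
                                            "betweenness", "node",
                                            "betweenness", g)
    }
    if (!is.null(results$tree_metrics)) {
      tm <- results$tree_metrics
      long <- rbindl(lapply(
        c("diameter", "leaf_fraction", "tree_hierarchy",
          "betweenness_max", "global_fc"),
        function(mm) {
          data.frame(subject = tm$subject, group = tm$group,
                     session = tm$session, metric = mm, value = tm[[mm]])
        }
      ))
      rows[[paste(g, "tree")]] <- add_family(long, "value", "metric",
                                             "tree_metrics", g)
    }
  }
  tab <- rbindl(rows)
  if (is.null(tab)) return(NULL)
  tab <- tab[!is.na(tab$p), ]
  # one correction family: every metric-level comparison of the study is
  # adjusted jointly, matching a single adjusted significance level of 0.05
  out <- cbind(tab, fdr_correct(tab$p)[, c("p_adj", "reject")])
  out[order(out$group, out$family, out$unit), ]
}

serialize_config <- function(config) {
  list(
    seed = config$seed,
    out_dir = config$out_dir,
    protocol = unclass(config$protocol),
    noise = unclass(config$noise),
    band = unclass(config$band),
    preprocess = config$preprocess,
    analyses = config$analyses,
    nbs = config$nbs,
    montage = list(labels = config$montage$labels,
                   region_map = as.list(config$montage$region_map)),
    coupling = lapply(config$coupling, function(cp) {
      lapply(seq_len(nrow(cp$entries)), function(i) as.list(cp$entries[i, ]))
    })
  )
}

#' @export
print.mst_results <- function(x, ...) {
  cat("<mst_results>\n")
  if (!is.null(x$tree_metrics)) {
    cat("  ", nrow(x$tree_metrics), " subject-session trees\n", sep = "")
  }
  if (length(x$nbs)) {
    for (g in names(x$nbs)) {
      cat("  NBS [", g, "]: ", length(x$nbs[[g]]$components),
          " component(s)\n", sep = "")
    }
  }
  invisible(x)
}
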