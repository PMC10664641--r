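# Scenario config I/O: a strict JSON dialect. Every object is serialized to
# plain lists (named numeric vectors become JSON objects, matrices become
# {labels, rows}) and validated key-by-key on the way back in, with a path
# into the document in every error message.

check_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_ng("unknown key(s) at ", path, ": ", paste(unknown, collapse = ", "))
  }
  invisible(x)
}

need_key <- function(x, key, path) {
  if (is.null(x[[key]])) stop_ng(path, ".", key, " required")
  x[[key]]
}

named_to_list <- function(x) as.list(x)

list_to_named <- function(x, path) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop_ng("expected a named mapping at ", path)
  }
  vapply(x, function(v) as.numeric(v), numeric(1))
}

matrix_to_list <- function(m) list(labels = rownames(m),
                                   rows = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))

list_to_matrix <- function(x, path) {
  labs <- unlist(need_key(x, "labels", path))
  rows <- need_key(x, "rows", path)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  if (nrow(m) != length(labs) || ncol(m) != length(labs)) {
    stop_ng(path, ": matrix shape does not match labels")
  }
  dimnames(m) <- list(labs, labs)
  m
}

env_to_list <- function(e) {
  list(desire = lapply(unclass(e$desire), named_to_list),
       influencing = lapply(unclass(e$influencing), named_to_list))
}

env_from_list <- function(x, path) {
  check_keys(x, c("desire", "influencing"), path)
  d <- need_key(x, "desire", path)
  check_keys(d, c("profit", "performance", "emotional", "easygoing", "altruistic"),
             paste0(path, ".desire"))
  v <- need_key(x, "influencing", path)
  check_keys(v, c("owner", "physical", "market", "legislative"),
             paste0(path, ".influencing"))
  owner_environment(
    do.call(desire_profile,
            lapply(stats::setNames(nm = c("profit", "performance", "emotional",
                                          "easygoing", "altruistic")),
                   function(k) list_to_named(d[[k]] %||% list(),
                                             paste0(path, ".desire.", k)))),
    do.call(influencing_variables,
            lapply(stats::setNames(nm = c("owner", "physical", "market", "legislative")),
                   function(k) list_to_named(v[[k]] %||% list(),
                                             paste0(path, ".influencing.", k)))))
}

merit_to_list <- function(m) {
  list(profit = list(fixed = m$profit$fixed,
                     fixed_mult = named_to_list(m$profit$fixed_mult),
                     base = named_to_list(m$profit$base),
                     mult = lapply(m$profit$mult, named_to_list)),
       quality = list(q0 = m$quality$q0, q = named_to_list(m$quality$q)),
       performance = list(omega = named_to_list(m$performance$omega),
                          opt = named_to_list(m$performance$opt),
                          tau_max = m$performance$tau_max),
       emotional = list(omega = named_to_list(m$emotional$omega),
                        opt = named_to_list(m$emotional$opt),
                        tau_max = m$emotional$tau_max),
       altruistic = list(breed_id = m$altruistic$breed_id,
                         omega = named_to_list(m$altruistic$omega),
                         opt = named_to_list(m$altruistic$opt),
                         tau_max = m$altruistic$tau_max),
       easygoing = list(omega = named_to_list(m$easygoing$omega),
                        omega_mon = named_to_list(m$easygoing$omega_mon)),
       weights = list(lambda = m$weights$lambda, w = unname(m$weights$w),
                      alpha = unname(m$weights$alpha)))
}

merit_from_list <- function(x, path, traits = NULL) {
  check_keys(x, c("profit", "quality", "performance", "emotional",
                  "altruistic", "easygoing", "weights"), path)
  rew <- function(k) {
    xx <- x[[k]] %||% list()
    check_keys(xx, c("omega", "opt", "tau_max", "breed_id"), paste0(path, ".", k))
    list(omega = list_to_named(xx$omega %||% list(), paste0(path, ".", k, ".omega")),
         opt = list_to_named(xx$opt %||% list(), paste0(path, ".", k, ".opt")),
         tau_max = xx$tau_max %||% 0, breed_id = xx$breed_id)
  }
  pr <- x$profit %||% list()
  check_keys(pr, c("fixed", "fixed_mult", "base", "mult"), paste0(path, ".profit"))
  qu <- x$quality %||% list()
  check_keys(qu, c("q0", "q"), paste0(path, ".quality"))
  eg <- x$easygoing %||% list()
  check_keys(eg, c("omega", "omega_mon"), paste0(path, ".easygoing"))
  wt <- x$weights %||% list()
  check_keys(wt, c("lambda", "w", "alpha"), paste0(path, ".weights"))
  merit_params(
    profit = list(fixed = pr$fixed %||% 0,
                  fixed_mult = list_to_named(pr$fixed_mult %||% list(),
                                             paste0(path, ".profit.fixed_mult")),
                  base = list_to_named(pr$base %||% list(), paste0(path, ".profit.base")),
                  mult = lapply(pr$mult %||% list(), function(m)
                    list_to_named(m, paste0(path, ".profit.mult")))),
    quality = list(q0 = qu$q0 %||% 0,
                   q = list_to_named(qu$q %||% list(), paste0(path, ".quality.q"))),
    performance = rew("performance"), emotional = rew("emotional"),
    altruistic = rew("altruistic"),
    easygoing = list(omega = list_to_named(eg$omega %||% list(),
                                           paste0(path, ".easygoing.omega")),
                     omega_mon = list_to_named(eg$omega_mon %||% list(),
                                               paste0(path, ".easygoing.omega_mon"))),
    weights = list(lambda = wt$lambda %||% 0, w = unlist(wt$w %||% c(1, 1, 1)),
                   alpha = unlist(wt$alpha %||% c(0, 1, 0))),
    traits = traits)
}

subniche_to_list <- function(s) {
  dist <- if (s$distribution$type == "atoms") {
    list(type = "atoms",
         atoms = lapply(s$distribution$atoms, function(a)
           list(prob = a$prob, environment = env_to_list(a$environment))))
  } else {
    list(type = "gaussian", base = env_to_list(s$distribution$base),
         mean = named_to_list(s$distribution$mean),
         cov = matrix_to_list(s$distribution$cov))
  }
  list(label = s$label, size = s$size, growth_rate = s$growth_rate,
       distribution = dist)
}

subniche_from_list <- function(x, path) {
  check_keys(x, c("label", "size", "growth_rate", "distribution"), path)
  d <- need_key(x, "distribution", path)
  dpath <- paste0(path, ".distribution")
  type <- need_key(d, "type", dpath)
  if (type == "atoms") {
    check_keys(d, c("type", "atoms"), dpath)
    atoms <- lapply(seq_along(d$atoms), function(i) {
      a <- d$atoms[[i]]
      apath <- paste0(dpath, ".atoms[", i, "]")
      check_keys(a, c("prob", "environment"), apath)
      list(prob = as.numeric(need_key(a, "prob", apath)),
           environment = env_from_list(need_key(a, "environment", apath),
                                       paste0(apath, ".environment")))
    })
    subniche(x$label, x$size, x$growth_rate, atoms = atoms)
  } else if (type == "gaussian") {
    check_keys(d, c("type", "base", "mean", "cov"), dpath)
    subniche(x$label, x$size, x$growth_rate,
             gaussian = list(base = env_from_list(need_key(d, "base", dpath),
                                                  paste0(dpath, ".base")),
                             mean = list_to_named(need_key(d, "mean", dpath),
                                                  paste0(dpath, ".mean")),
                             cov = list_to_matrix(need_key(d, "cov", dpath),
                                                  paste0(dpath, ".cov"))))
  } else stop_ng(dpath, ".type must be \"atoms\" or \"gaussian\"")
}

exclusion_to_list <- function(ex) {
  if (ex$type == "halfspace") {
    list(label = ex$label, type = "halfspace", coef = named_to_list(ex$coef),
         rhs = ex$rhs)
  } else {
    list(label = ex$label, type = "box", lower = named_to_list(ex$lower),
         upper = named_to_list(ex$upper))
  }
}

exclusion_from_list <- function(x, path) {
  type <- need_key(x, "type", path)
  if (type == "halfspace") {
    check_keys(x, c("label", "type", "coef", "rhs"), path)
    exclusion_halfspace(x$label, list_to_named(x$coef, paste0(path, ".coef")), x$rhs)
  } else if (type == "box") {
    check_keys(x, c("label", "type", "lower", "upper"), path)
    exclusion_box(x$label, list_to_named(x$lower, paste0(path, ".lower")),
                  list_to_named(x$upper, paste0(path, ".upper")))
  } else stop_ng(path, ".type must be \"halfspace\" or \"box\"")
}

scenario_to_list <- function(scn) {
  st <- scn$state
  list(
    name = scn$name,
    seed = scn$seed,
    traits = lapply(seq_len(nrow(st$trait_space)), function(i)
      as.list(st$trait_space[i, , drop = FALSE])),
    state = list(
      mu_c = named_to_list(st$mu_c),
      current_goal = if (is.null(st$current_goal)) NULL else named_to_list(st$current_goal),
      reaction_norm = if (is.null(st$reaction_norm)) NULL else
        list(variables = colnames(st$reaction_norm),
             rows = lapply(seq_len(nrow(st$reaction_norm)), function(i)
               unname(st$reaction_norm[i, ])))),
    genetics = list(G = matrix_to_list(st$genetics$G),
                    P = matrix_to_list(st$genetics$P)),
    niche = list(subniches = lapply(scn$niche$subniches, subniche_to_list),
                 producer_env = env_to_list(scn$niche$producer_env)),
    merit = lapply(scn$merit, merit_to_list),
    validity = unclass(scn$validity),
    optimization = c(scn$optimization[setdiff(names(scn$optimization), "exclusions")],
                     list(exclusions = lapply(scn$optimization$exclusions,
                                              exclusion_to_list))))
}

scenario_from_list <- function(x) {
  check_keys(x, c("name", "seed", "traits", "state", "genetics", "niche",
                  "merit", "validity", "optimization"), "$")
  traits <- do.call(rbind, lapply(x$traits, function(tr)
    data.frame(label = tr$label, category = tr$category, unit = tr$unit,
               stringsAsFactors = FALSE)))
  ts <- trait_space(traits)
  gn <- need_key(x, "genetics", "$")
  check_keys(gn, c("G", "P"), "$.genetics")
  gen <- genetic_parameters(list_to_matrix(need_key(gn, "G", "$.genetics"), "$.genetics.G"),
                            list_to_matrix(need_key(gn, "P", "$.genetics"), "$.genetics.P"))
  stt <- need_key(x, "state", "$")
  check_keys(stt, c("mu_c", "current_goal", "reaction_norm"), "$.state")
  rn <- NULL
  if (!is.null(stt$reaction_norm)) {
    check_keys(stt$reaction_norm, c("variables", "rows"), "$.state.reaction_norm")
    rn <- do.call(rbind, lapply(stt$reaction_norm$rows, function(r) as.numeric(unlist(r))))
    dimnames(rn) <- list(ts$label, unlist(stt$reaction_norm$variables))
  }
  st <- breed_state(ts, list_to_named(need_key(stt, "mu_c", "$.state"), "$.state.mu_c"),
                    gen, reaction_norm = rn,
                    current_goal = if (is.null(stt$current_goal)) NULL else
                      list_to_named(stt$current_goal, "$.state.current_goal"))
  ni <- need_key(x, "niche", "$")
  check_keys(ni, c("subniches", "producer_env"), "$.niche")
  niche <- breed_niche(
    lapply(seq_along(ni$subniches), function(i)
      subniche_from_list(ni$subniches[[i]], paste0("$.niche.subniches[", i, "]"))),
    env_from_list(need_key(ni, "producer_env", "$.niche"), "$.niche.producer_env"))
  merit <- lapply(stats::setNames(nm = names(x$merit)), function(lab)
    merit_from_list(x$merit[[lab]], paste0("$.merit.", lab), traits = ts))
  vl <- need_key(x, "validity", "$")
  check_keys(vl, c("c_b", "N_min", "a_ref", "kappa"), "$.validity")
  opt <- need_key(x, "optimization", "$")
  check_keys(opt, c("intensity", "generations", "gen_interval", "horizon_years",
                    "search_k", "exclusions"), "$.optimization")
  opt$exclusions <- lapply(seq_along(opt$exclusions), function(i)
    exclusion_from_list(opt$exclusions[[i]], paste0("$.optimization.exclusions[", i, "]")))
  opt$generations <- as.integer(opt$generations)
  scenario(name = x$name, state = st, niche = niche, merit = merit,
           validity = validity_params(vl$c_b, vl$N_min, vl$a_ref %||% 0,
                                      vl$kappa %||% 0),
           optimization = opt, seed = as.integer(x$seed %||% 1L))
}

#' Save a scenario as a JSON config file
#'
#' @param scn a [scenario].
#' @param path output file path.
#' @export
save_scenario <- function(scn, path) {
  # digits = I(17): doubles survive the round trip bit-exactly
  jsonlite::write_json(scenario_to_list(scn), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null")
  invisible(path)
}

#' Load and validate a scenario from a JSON config file
#'
#' Strict: unknown keys, label mismatches and invariant violations are
#' errors that name the offending path in the document.
#'
#' @param path config file path.
#' @return A [scenario].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_ng("scenario file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  scenario_from_list(x)
}

#' Write a data frame as CSV with a provenance header
#'
#' Prepends a `# seed=... config=...` comment line so every output records
#' the seed and a fingerprint of the configuration that produced it.
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed integer seed to stamp.
#' @param config_hash fingerprint string (e.g. from the scenario JSON).
#' @export
write_csv_stamped <- function(df, path, seed, config_hash = "") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", as.integer(seed), config_hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a CSV written by [write_csv_stamped()]
#'
#' @param path file path.
#' @export
read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export sampled environments as a data frame (one column per dimension)
#'
#' @param envs list of [owner_environment] (e.g. from [sample_environments()]).
#' @return data.frame with desire and influencing dimensions as columns and
#'   a `subniche` column when the sample carries source labels.
#' @export
environments_to_df <- function(envs) {
  rows <- lapply(envs, function(e) {
    d <- unlist(lapply(unclass(e$desire), function(x) x))
    names(d) <- unlist(lapply(unclass(e$desire), names))
    v <- iv_flatten(e$influencing)
    c(d, v)
  })
  out <- as.data.frame(do.call(rbind, rows))
  sub <- attr(envs, "subniche")
  if (!is.null(sub)) out$subniche <- sub
  out
}

#' Export per-trait merit parameters as a data frame
#'
#' @param params a [merit_params].
#' @param traits a [trait_space].
#' @param v optional [influencing_variables] at which profit coefficients
#'   are evaluated.
#' @return data.frame (trait, omega, opt, omega_mon, profit_base, quality_q).
#' @export
merit_params_to_df <- function(params, traits, v = NULL) {
  labs <- trait_labels(traits)
  pick <- function(x, default = NA_real_) {
    out <- stats::setNames(rep(default, length(labs)), labs)
    hit <- intersect(names(x), labs)
    out[hit] <- x[hit]
    out
  }
  omega <- pick(c(params$performance$omega, params$emotional$omega,
                  params$altruistic$omega))
  opt <- pick(c(params$performance$opt, params$emotional$opt,
                params$altruistic$opt))
  prof <- if (is.null(v)) pick(params$profit$base, 0) else
    pick(profit_coefficients(params, v, labs), 0)
  data.frame(trait = labs, omega = omega, opt = opt,
             omega_mon = pick(params$easygoing$omega_mon),
             profit_base = prof, quality_q = pick(params$quality$q, 0),
             row.names = NULL)
}
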