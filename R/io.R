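#' Serialize parameters to a configuration file
#'
#' Parameters are written as a structured YAML document with sections
#' `filament`, `potentials`, `dynamics`, `units` — the package's
#' configuration dialect.  [read_params_yaml()] restores a fully resolved
#' [model_params()] object.
#'
#' @param params an [model_params()].
#' @param path file path (.yaml).
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "awlc_params"))
  doc <- list(
    filament = list(n_bonds = params$spec$n_bonds, r0 = params$spec$r0,
                    Lf = params$spec$Lf, dtheta = params$spec$dtheta),
    potentials = list(k_bond = params$k_bond, k_bend = params$k_bend,
                      epsilon = params$epsilon, sigma = params$sigma,
                      r_cut = params$r_cut,
                      attraction = params$attraction),
    dynamics = list(v0 = params$v0, f_p = params$f_p, gamma = params$gamma,
                    kBT = params$kBT, dt = params$dt),
    units = list(nm_per_d = params$units$nm_per_d,
                 s_per_tau = params$units$s_per_tau))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  for (sec in c("filament", "potentials", "dynamics"))
    if (is.null(doc[[sec]]))
      stop("config is missing required section '", sec, "'")
  need <- function(sec, field) {
    v <- doc[[sec]][[field]]
    if (is.null(v)) stop("config is missing required field ", sec, ".", field)
    v
  }
  spec <- filament_spec(need("filament", "n_bonds"),
                        dtheta = need("filament", "dtheta"),
                        r0 = need("filament", "r0"))
  units <- if (!is.null(doc$units))
    unit_system(doc$units$nm_per_d, doc$units$s_per_tau) else unit_system()
  p <- model_params(spec,
                    v0 = need("dynamics", "v0"),
                    gamma = need("dynamics", "gamma"),
                    k_bend = need("potentials", "k_bend"),
                    kBT = need("dynamics", "kBT"),
                    k_bond = need("potentials", "k_bond"),
                    epsilon = need("potentials", "epsilon"),
                    attraction = isTRUE(doc$potentials$attraction),
                    dt = need("dynamics", "dt"),
                    units = units)
  # honour an explicit cutoff (overrides the attraction-derived default)
  if (!is.null(doc$potentials$r_cut)) p$r_cut <- doc$potentials$r_cut
  p
}

#' Write / read trajectories as plain text
#'
#' One self-describing text file: a YAML header (parameters, seed,
#' geometry, equilibration flag) followed by per-frame blocks
#' `FRAME <time>` with one `x<TAB>y` line per bead in filament-contiguous
#' order.
#'
#' @param traj an `awlc_traj`.
#' @param path output file.
#' @return `path` invisibly (`read_trajectory` returns the `awlc_traj`).
#' @export
write_trajectory <- function(traj, path) {
  st <- traj$frames[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# activewlc trajectory v1", con)
  hdr <- list(n_bonds = st$M - 1L, box_L = st$box_L,
              n_filaments = n_filaments(st), seed = traj$seed,
              equilibration_tau = traj$equilibration_tau,
              params = yaml::yaml.load(yaml::as.yaml(.params_doc(traj$params), precision = 15)))
  writeLines(paste0("#yaml ", strsplit(yaml::as.yaml(hdr, precision = 15), "\n")[[1]]), con)
  writeLines("#end", con)
  for (k in seq_along(traj$frames)) {
    writeLines(sprintf("FRAME %.15g", traj$times[k]), con)
    P <- traj$frames[[k]]$pos
    writeLines(sprintf("%.10g\t%.10g", P[, 1], P[, 2]), con)
  }
  invisible(path)
}

.params_doc <- function(params) {
  list(filament = list(n_bonds = params$spec$n_bonds, r0 = params$spec$r0,
                       dtheta = params$spec$dtheta),
       potentials = list(k_bond = params$k_bond, k_bend = params$k_bend,
                         epsilon = params$epsilon, r_cut = params$r_cut,
                         attraction = params$attraction),
       dynamics = list(v0 = params$v0, gamma = params$gamma,
                       kBT = params$kBT, dt = params$dt))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# activewlc trajectory"))
    stop("not an activewlc trajectory file (versioned format header missing)")
  hend <- match("#end", lines)
  hdr <- yaml::yaml.load(paste(sub("^#yaml ", "", lines[2:(hend - 1)]),
                               collapse = "\n"))
  body <- lines[(hend + 1):length(lines)]
  fstart <- grep("^FRAME ", body)
  times <- as.numeric(sub("^FRAME ", "", body[fstart]))
  ends <- c(fstart[-1] - 1L, length(body))
  frames <- lapply(seq_along(fstart), function(k) {
    chunk <- body[(fstart[k] + 1):ends[k]]
    xy <- matrix(as.numeric(unlist(strsplit(chunk, "\t"))), ncol = 2,
                 byrow = TRUE)
    system_state(xy, hdr$n_bonds, hdr$box_L, time = times[k])
  })
  pd <- hdr$params
  spec <- filament_spec(pd$filament$n_bonds, dtheta = pd$filament$dtheta,
                        r0 = pd$filament$r0)
  params <- model_params(spec, v0 = pd$dynamics$v0,
                         gamma = pd$dynamics$gamma,
                         k_bend = pd$potentials$k_bend,
                         kBT = pd$dynamics$kBT,
                         k_bond = pd$potentials$k_bond,
                         epsilon = pd$potentials$epsilon,
                         attraction = isTRUE(pd$potentials$attraction),
                         dt = pd$dynamics$dt)
  params$r_cut <- pd$potentials$r_cut
  structure(list(frames = frames, times = times, params = params,
                 seed = hdr$seed,
                 equilibration_tau = hdr$equilibration_tau),
            class = "awlc_traj")
}

#' Export a trajectory to XYZ for external viewers
#'
#' Plain multi-frame XYZ: bead count, a comment line with the time, then
#' `F<filament> x y 0` per bead.
#'
#' @param traj an `awlc_traj`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fil <- filament_of(traj$frames[[1]])
  for (k in seq_along(traj$frames)) {
    P <- traj$frames[[k]]$pos
    writeLines(as.character(nrow(P)), con)
    writeLines(sprintf("t = %g tau", traj$times[k]), con)
    writeLines(sprintf("F%d %.6f %.6f 0", fil, P[, 1], P[, 2]), con)
  }
  invisible(path)
}

#' Run manifest
#'
#' Every simulation or analysis driven through the command-line interface
#' writes one manifest recording the resolved parameters, the seed, input
#' and output paths, the frame schedule and the wall-clock time — enough to
#' reproduce the outputs bit for bit with the same build.
#'
#' @param path manifest path (.yaml).
#' @param params an [model_params()].
#' @param seed integer seed.
#' @param inputs,outputs character vectors of paths.
#' @param extra named list of additional fields (schedule, thresholds...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, seed, inputs = character(0),
                           outputs = character(0), extra = list()) {
  doc <- c(list(
    tool = "activewlc",
    version = as.character(utils::packageVersion("activewlc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs), outputs = as.list(outputs),
    params = .params_doc(params)), extra)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
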