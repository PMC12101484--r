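#' Write a trajectory dump to disk
#'
#' Two text dialects are supported and round-trip all numeric fields at
#' full double precision:
#' \describe{
#'   \item{`"xyz"`}{extended-XYZ: per frame a bead count line, a comment
#'     line `Lattice="Lx 0 0 0 Ly 0 0 0 Lz" step=S
#'     Properties=species:S:1:pos:R:3:velo:R:3:id:I:1:chain:I:1:active:I:1`,
#'     then one line per bead
#'     `C x y z vx vy vz id chain active`.}
#'   \item{`"dump"`}{columnar: per frame `STEP S` and `N n` header lines
#'     followed by `id chain active x y z vx vy vz` rows.}
#' }
#' A JSON metadata sidecar (`<path>.meta.json`) stores the simulation
#' parameters.
#'
#' @param dump a `trajectory_dump`.
#' @param path output file path.
#' @param format `"xyz"` or `"dump"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(dump, path, format = c("xyz", "dump")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(dump$snapshots)) {
    st <- dump$snapshots[[k]]
    n <- nrow(st$positions)
    id <- seq_len(n)
    act <- as.integer(st$active[st$chain_id])
    body <- paste(fmt17(st$positions[, 1]), fmt17(st$positions[, 2]),
                  fmt17(st$positions[, 3]), fmt17(st$velocities[, 1]),
                  fmt17(st$velocities[, 2]), fmt17(st$velocities[, 3]))
    if (format == "xyz") {
      writeLines(as.character(n), con)
      writeLines(sprintf(
        paste0("Lattice=\"%g 0 0 0 %g 0 0 0 %g\" step=%g Properties=",
               "species:S:1:pos:R:3:velo:R:3:id:I:1:chain:I:1:active:I:1"),
        dump$params$box[1], dump$params$box[2], dump$params$box[3],
        st$step), con)
      writeLines(paste("C", body, id, st$chain_id, act), con)
    } else {
      writeLines(sprintf("STEP %g", st$step), con)
      writeLines(sprintf("N %d", n), con)
      writeLines(paste(id, st$chain_id, act, body), con)
    }
  }
  meta <- dump$params
  class(meta) <- NULL
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory dump written by [write_trajectory()]
#'
#' @param path trajectory file path; the `<path>.meta.json` sidecar must
#'   be present.
#' @param format `"xyz"` or `"dump"`.
#' @return a `trajectory_dump`.
#' @export
read_trajectory <- function(path, format = c("xyz", "dump")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  # JSON round-trips whole numbers as integers; parameters are doubles
  num_fields <- c("box", "epsilon", "fene_K_eps", "fene_R0", "lj_cutoff",
                  "dt", "damping", "f_act", "f_passive", "bias_steps",
                  "bias_k_eps", "total_steps", "dump_every",
                  "analysis_start", "skin")
  for (k in num_fields) meta[[k]] <- as.numeric(meta[[k]])
  params <- do.call(sim_params, list(
    n_chains = meta$n_chains, beads_per_chain = meta$beads_per_chain,
    box = meta$box, epsilon = meta$epsilon, fene_K = meta$fene_K_eps,
    fene_R0 = meta$fene_R0, lj_cutoff = meta$lj_cutoff,
    shift_lj = meta$shift_lj, bonded_lj = meta$bonded_lj, dt = meta$dt,
    damping = meta$damping, f_act = meta$f_act, f_passive = meta$f_passive,
    bias_steps = meta$bias_steps, bias_k = meta$bias_k_eps,
    total_steps = meta$total_steps, dump_every = meta$dump_every,
    analysis_start = meta$analysis_start, seed = meta$seed,
    skin = meta$skin, scale = meta$scale))
  lines <- readLines(path)
  snaps <- list()
  steps <- numeric(0)
  i <- 1
  frame <- 0
  while (i <= length(lines)) {
    frame <- frame + 1
    if (format == "xyz") {
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n) || i + 1 > length(lines))
        stop("malformed frame header at frame ", frame)
      hdr <- lines[i + 1]
      step <- as.numeric(sub(".*step=([-0-9.e+]+).*", "\\1", hdr))
      if (i + 1 + n > length(lines))
        stop("truncated trajectory at frame ", frame)
      rows <- strsplit(lines[(i + 2):(i + 1 + n)], " ", fixed = TRUE)
      i <- i + 2 + n
      m <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:10))),
                  ncol = 9, byrow = TRUE)
      pos <- m[, 1:3, drop = FALSE]
      vel <- m[, 4:6, drop = FALSE]
    } else {
      if (!startsWith(lines[i], "STEP "))
        stop("malformed frame header at frame ", frame)
      step <- as.numeric(sub("STEP ", "", lines[i]))
      n <- as.integer(sub("N ", "", lines[i + 1]))
      if (is.na(n) || i + 1 + n > length(lines))
        stop("truncated trajectory at frame ", frame)
      rows <- strsplit(lines[(i + 2):(i + 1 + n)], " ", fixed = TRUE)
      i <- i + 2 + n
      m <- matrix(as.numeric(unlist(lapply(rows, `[`, 4:9))),
                  ncol = 6, byrow = TRUE)
      pos <- m[, 1:3, drop = FALSE]
      vel <- m[, 4:6, drop = FALSE]
    }
    st <- system_state(pos, vel, params, step = step)
    snaps[[frame]] <- st
    steps <- c(steps, step)
  }
  dump <- list(params = params, steps = steps, snapshots = snaps)
  class(dump) <- "trajectory_dump"
  dump
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment.  Keys must match [sim_params()] field names; unknown keys are
#' rejected.
#'
#' @param path config file path.
#' @return a `sim_params` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  allowed <- c("n_chains", "beads_per_chain", "box", "epsilon", "fene_K",
               "fene_R0", "lj_cutoff", "shift_lj", "bonded_lj", "dt",
               "damping", "f_act", "f_passive", "bias_steps", "bias_k",
               "total_steps", "dump_every", "analysis_start", "seed",
               "skin", "scale")
  bad <- setdiff(keys, allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  for (k in names(args)) {
    if (k == "scale") next
    if (k == "box") args[[k]] <- as.numeric(strsplit(args[[k]], "[ ,]+")[[1]])
    else if (k %in% c("shift_lj", "bonded_lj"))
      args[[k]] <- toupper(args[[k]]) %in% c("TRUE", "T", "1", "YES")
    else args[[k]] <- as.numeric(args[[k]])
  }
  do.call(sim_params, args)
}

#' Write a resolved configuration beside run outputs
#'
#' @param params a `sim_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  lines <- c(sprintf("n_chains = %d", params$n_chains),
             sprintf("beads_per_chain = %d", params$beads_per_chain),
             sprintf("box = %.17g %.17g %.17g", params$box[1],
                     params$box[2], params$box[3]),
             sprintf("epsilon = %.17g", params$epsilon),
             sprintf("fene_K = %.17g", params$fene_K_eps),
             sprintf("fene_R0 = %.17g", params$fene_R0),
             sprintf("lj_cutoff = %.17g", params$lj_cutoff),
             sprintf("shift_lj = %s", params$shift_lj),
             sprintf("bonded_lj = %s", params$bonded_lj),
             sprintf("dt = %.17g", params$dt),
             sprintf("damping = %.17g", params$damping),
             sprintf("f_act = %.17g", params$f_act),
             sprintf("f_passive = %.17g", params$f_passive),
             sprintf("bias_steps = %.17g", params$bias_steps),
             sprintf("bias_k = %.17g", params$bias_k_eps),
             sprintf("total_steps = %.17g", params$total_steps),
             sprintf("dump_every = %.17g", params$dump_every),
             sprintf("analysis_start = %.17g", params$analysis_start),
             sprintf("seed = %d", params$seed),
             sprintf("skin = %.17g", params$skin),
             sprintf("scale = %s", params$scale))
  writeLines(lines, path)
  invisible(path)
}
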