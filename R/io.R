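#' Write conformations to an XYZ trajectory
#'
#' One frame per conformation, element tag "C", with the comment line
#' carrying \code{mcs}, \code{replica} and the surface energy when the
#' input is a \code{sample_set}. Coordinates are written with 17
#' significant digits so a read-back reproduces them bit-exactly.
#'
#' @param x a position matrix, list of them, or a \code{sample_set}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_xyz <- function(x, path) {
  confs <- as_conformation_list(x)
  meta <- if (inherits(x, "sample_set")) {
    sprintf("mcs=%.0f replica=%d u_surf=%.17g",
            x$mcs, x$replica, x$energies[, "u_surf"])
  } else {
    sprintf("frame=%d", seq_along(confs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(confs)) {
    p <- confs[[i]]
    writeLines(c(as.character(nrow(p)), meta[i]), con)
    writeLines(sprintf("C %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()] (or any standard XYZ).
#' @return a list of position matrices with the per-frame comment lines in
#'   attribute \code{"comments"}. Malformed files (truncated frames,
#'   non-numeric bead counts, bead-count mismatches between header and
#'   body) raise errors naming the offending frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  confs <- list()
  comments <- character(0)
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nb <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nb) || nb < 1)
      stop(sprintf("frame %d: invalid bead count line '%s'", frame, lines[i]),
           call. = FALSE)
    if (i + 1L + nb > length(lines))
      stop(sprintf("frame %d: truncated (expected %d beads)", frame, nb),
           call. = FALSE)
    comments <- c(comments, lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + nb)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) != 4))
      stop(sprintf("frame %d: malformed coordinate line", frame), call. = FALSE)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("frame %d: non-numeric coordinates", frame), call. = FALSE)
    confs[[frame]] <- xyz
    i <- i + 2L + nb
  }
  if (frame == 0L) stop("no frames found", call. = FALSE)
  attr(confs, "comments") <- comments
  confs
}

#' Persist a sample set as a directory container
#'
#' Writes a plain-text container with the trajectory in
#' \code{positions.xyz}, the per-sample energy components in
#' \code{energies.csv}, and all metadata (model parameters, run schedule,
#' restart log, sample indexing) in \code{meta.json}. A read-back
#' reproduces positions and energies to full stored precision.
#'
#' @param ss a \code{sample_set}.
#' @param dir container directory (created if needed).
#' @return \code{read_sample_set()} returns a \code{sample_set};
#'   \code{write_sample_set()} the directory, invisibly.
#' @export
write_sample_set <- function(ss, dir) {
  stopifnot(inherits(ss, "sample_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(ss, file.path(dir, "positions.xyz"))
  en <- as.data.frame(ss$energies)
  utils::write.csv(data.frame(lapply(en, function(v) sprintf("%.17g", v))),
                   file.path(dir, "energies.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(params = {p <- unclass(ss$params); p$r0 <- NULL; p},
               schedule = unclass(ss$schedule),
               mcs = ss$mcs, replica = ss$replica,
               restart_log = ss$restart_log,
               n_samples = n_samples(ss))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sample_set
#' @param dir container directory.
#' @export
read_sample_set <- function(dir) {
  need <- file.path(dir, c("positions.xyz", "energies.csv", "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("not a sample_set container; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  confs <- read_xyz(file.path(dir, "positions.xyz"))
  if (length(confs) != meta$n_samples)
    stop(sprintf("sample count mismatch: meta says %d, trajectory has %d",
                 meta$n_samples, length(confs)), call. = FALSE)
  en <- utils::read.csv(file.path(dir, "energies.csv"))
  params <- do.call(model_params, meta$params)
  schedule <- do.call(run_schedule, meta$schedule)
  nb <- params$n_bonds + 1L
  pos <- array(NA_real_, c(length(confs), nb, 3))
  for (i in seq_along(confs)) pos[i, , ] <- confs[[i]]
  ss <- list(positions = pos, energies = as.matrix(en),
             mcs = as.numeric(meta$mcs), replica = as.integer(meta$replica),
             params = params, schedule = schedule,
             restart_log = as.data.frame(meta$restart_log))
  class(ss) <- "sample_set"
  ss
}
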