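#' Read conformations from an XYZ or PDB file
#'
#' XYZ files follow the xmol convention (atom count, comment line, then
#' `element x y z` records; multiple frames concatenated).  PDB files are
#' parsed with bio3d; multi-model files yield multi-frame pools.  Beads are
#' written as CA atoms of sequential residues.
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the extension.
#' @return A [conformation_pool()]; element/bead labels are kept in the
#'   `labels` attribute.
#' @export
read_conformations <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    "xyz" = .read_xyz(path),
    "pdb" = .read_pdb_pool(path),
    stop("unsupported conformation format: ", format))
}

#' Write a pool or path of conformations
#'
#' @param pool A [conformation_pool()], [make_path()] path, trajectory, or
#'   a single conformation matrix.
#' @param path Output file path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the extension.
#' @param labels Optional per-particle element/bead labels (default "C").
#' @return The output path, invisibly.
#' @export
write_conformations <- function(pool, path, format = NULL, labels = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  pool <- .as_pool3d(pool)
  labels <- labels %||% rep("C", pool$n_particles)
  switch(format,
    "xyz" = .write_xyz(pool, path, labels),
    "pdb" = .write_pdb_pool(pool, path),
    stop("unsupported conformation format: ", format))
  invisible(path)
}

# coerce path / trajectory / matrix inputs to a 3D-coordinate pool
.as_pool3d <- function(x) {
  if (inherits(x, "conformation_pool")) pool <- x
  else if (inherits(x, "md_trajectory")) pool <- conformation_pool(x$coords)
  else if (inherits(x, "tpath")) {
    frames <- lapply(seq_len(nrow(x)), function(i) path_image(x, i))
    pool <- conformation_pool(frames)
  } else if (is.matrix(x)) pool <- conformation_pool(list(x))
  else stop("cannot interpret input as conformations")
  if (pool$ndim < 3) {
    padded <- array(0, c(pool$n_frames, pool$n_particles, 3))
    padded[, , seq_len(pool$ndim)] <- pool$coords
    pool <- conformation_pool(padded, frame_id = pool$frame_id,
                              source = pool$source)
  }
  pool
}

.read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("%s: line %d: expected an atom count", path, i))
    nat <- as.integer(trimws(lines[i]))
    if (i + 1 + nat > length(lines))
      stop(sprintf("%s: line %d: truncated frame (%d atoms declared)",
                   path, i, nat))
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad))
      stop(sprintf("%s: line %d: malformed atom record", path, i + 1 + bad[1]))
    lab <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("%s: non-numeric coordinates near line %d", path, i + 2))
    if (is.null(labels)) labels <- lab
    if (nat != length(labels))
      stop(path, ": mixed particle counts across frames")
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nat
  }
  if (!length(frames)) stop(path, ": no frames found")
  pool <- conformation_pool(frames)
  attr(pool, "labels") <- labels
  pool
}

.write_xyz <- function(pool, path, labels) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(pool$n_frames)) {
    writeLines(c(as.character(pool$n_particles),
                 sprintf("frame %d", pool$frame_id[f])), con)
    fr <- matrix(pool$coords[f, , ], ncol = 3)
    writeLines(sprintf("%s %.10g %.10g %.10g", labels,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
}

.read_pdb_pool <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  nat <- ncol(xyz) / 3
  coords <- array(0, c(nf, nat, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  pool <- conformation_pool(coords)
  attr(pool, "labels") <- pdb$atom$elety
  pool
}

.write_pdb_pool <- function(pool, path) {
  nat <- pool$n_particles
  xyz <- matrix(0, pool$n_frames, nat * 3)
  for (f in seq_len(pool$n_frames))
    xyz[f, ] <- as.numeric(t(matrix(pool$coords[f, , ], ncol = 3)))
  bio3d::write.pdb(pdb = NULL, xyz = bio3d::as.xyz(xyz), file = path,
                   resno = seq_len(nat), resid = rep("ALA", nat),
                   elety = rep("CA", nat), chain = rep("A", nat))
}

#' Write / read a hills log in the HILLS text convention
#'
#' Whitespace-delimited text with a `#! FIELDS` header listing time,
#' per-CV center and sigma columns, height and the bias factor — column
#' compatible with the de-facto HILLS file convention of metadynamics
#' engines (the walker id is carried in an extra trailing column).
#'
#' @param hills A [hills_log()].
#' @param path Output path.
#' @param params The run's [wt_params()] (for the bias factor column).
#' @return `write_hills`: the path, invisibly. `read_hills`: a
#'   [hills_log()].
#' @export
write_hills <- function(hills, path, params) {
  n_cv <- attr(hills, "n_cv")
  cvn <- paste0("cv", seq_len(n_cv))
  header <- paste("#! FIELDS time", paste(cvn, collapse = " "),
                  paste(paste0("sigma_", cvn), collapse = " "),
                  "height biasf walker")
  df <- data.frame(time = hills$time,
                   .hills_centers(hills), .hills_sigmas(hills),
                   height = hills$height,
                   biasf = rep(params$bias_factor, nrow(hills)),
                   walker = hills$walker)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#!")) stop(path, ": missing HILLS FIELDS header")
  fields <- strsplit(sub("^#!\\s*FIELDS\\s*", "", header), "\\s+")[[1]]
  df <- utils::read.table(path, skip = 1, col.names = fields)
  n_cv <- sum(grepl("^cv", fields) & !grepl("^sigma", fields))
  out <- hills_log(n_cv)
  cvn <- paste0("cv", seq_len(n_cv))
  row <- data.frame(time = df$time, walker = as.integer(df$walker))
  for (k in seq_len(n_cv)) row[[paste0("center.", k)]] <- df[[cvn[k]]]
  for (k in seq_len(n_cv))
    row[[paste0("sigma.", k)]] <- df[[paste0("sigma_", cvn[k])]]
  row$height <- df$height
  structure(row, n_cv = n_cv, class = c("hills_log", "data.frame"))
}

#' Tabular writers for analysis results
#'
#' Plain TSV writers for the toolkit's tabular outputs: string checkpoints
#' (iteration, image, CV index, target), PMF profiles (alpha, F),
#' convergence traces, cluster assignments, network edge lists, RMSF
#' profiles, driving profiles, contact maps, and gridded surfaces.
#'
#' @param x The object to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' @rdname tsv_io
#' @export
write_string_checkpoint <- function(x, path) {
  targets <- if (inherits(x, "string_state")) x$targets else as.matrix(x)
  df <- data.frame(image = rep(seq_len(nrow(targets)), ncol(targets)),
                   cv = rep(seq_len(ncol(targets)), each = nrow(targets)),
                   target = as.numeric(targets))
  write_tsv(df, path)
}

#' @rdname tsv_io
#' @export
read_string_checkpoint <- function(path) {
  df <- read_tsv(path)
  n_img <- max(df$image); n_cv <- max(df$cv)
  targets <- matrix(NA_real_, n_img, n_cv)
  targets[cbind(df$image, df$cv)] <- df$target
  targets
}

#' @rdname tsv_io
#' @export
write_fes <- function(fes, path) {
  ax <- fes$axes
  if (length(ax) == 1) {
    df <- data.frame(cv1 = ax[[1]], F = as.numeric(fes$F))
  } else {
    df <- expand.grid(cv1 = ax[[1]], cv2 = ax[[2]])
    df$F <- as.numeric(fes$F)
  }
  write_tsv(df, path)
}

#' @rdname tsv_io
#' @export
write_density_map <- function(dm, path) {
  df <- expand.grid(x = dm$x, y = dm$y)
  df$density <- as.numeric(dm$density)
  write_tsv(df, path)
}

#' Serialize / parse a contact map as TSV
#'
#' Columns: pair indices, one `d0` column per reference state, and `r0`.
#'
#' @param spec A [contact_map_spec()].
#' @param path File path.
#' @return `write_contact_map`: path invisibly; `read_contact_map`: the
#'   spec.
#' @export
write_contact_map <- function(spec, path) {
  df <- data.frame(i = spec$pairs[, 1], j = spec$pairs[, 2])
  for (s in colnames(spec$d0)) df[[paste0("d0_", s)]] <- spec$d0[, s]
  df$r0 <- spec$r0
  write_tsv(df, path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  df <- read_tsv(path)
  d0_cols <- grep("^d0_", names(df), value = TRUE)
  d0 <- as.matrix(df[, d0_cols, drop = FALSE])
  colnames(d0) <- sub("^d0_", "", d0_cols)
  contact_map_spec(cbind(df$i, df$j), d0, r0 = df$r0[1])
}
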