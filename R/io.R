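#' Read and write COLVAR-dialect tables
#'
#' Whitespace-separated scalar time series with a `#! FIELDS time ...`
#' header, the PLUMED interchange convention. Additional `#! SET key value`
#' lines are preserved as attributes.
#'
#' @param x data.frame whose first column should be `time` (ps)
#' @param path file path
#' @param meta optional named list written as `#! SET` lines
#' @return `readColvar` returns a data.frame with any `#! SET` entries in
#'   `attr(, "meta")`
#' @export
writeColvar <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(colnames(x), collapse = " ")), con)
  for (k in names(meta))
    writeLines(paste("#! SET", k, format(meta[[k]], digits = 17)), con)
  utils::write.table(format(x, digits = 12, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeColvar
#' @export
readColvar <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!", lines, value = TRUE)
  fields <- strsplit(sub("^#! FIELDS ", "", hdr[grepl("^#! FIELDS", hdr)]),
                     "\\s+")[[1]]
  meta <- list()
  for (s in hdr[grepl("^#! SET", hdr)]) {
    tok <- strsplit(sub("^#! SET ", "", s), "\\s+")[[1]]
    meta[[tok[1]]] <- utils::type.convert(tok[2], as.is = TRUE)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, col.names = fields)
  attr(df, "meta") <- meta
  df
}

#' Write / read XYZ trajectories
#'
#' Plain multi-frame XYZ: per frame an atom count, a comment line carrying
#' the time and box, and one `<name> x y z` row per particle (nm).
#'
#' @param traj a [Trajectory-class]
#' @param path file path
#' @param names per-particle labels; defaults to site types + solute beads
#' @export
writeXyz <- function(traj, path, names = NULL) {
  sys <- traj@system
  n <- dim(traj@frames)[2]
  d <- dim(traj@frames)[3]
  if (is.null(names)) {
    names <- rep("X", n)
    if (length(sys@siteTypes)) names[sys@membraneIdx] <- sys@siteTypes
    if (length(sys@soluteIdx)) names[sys@soluteIdx] <- "SOL"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(traj@frames)[1])) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time= %.6f box= %s", traj@times[t],
                       paste(format(sys@box), collapse = " ")), con)
    xyz <- matrix(0, n, 3)
    xyz[, seq_len(d)] <- traj@frames[t, , ]
    writeLines(sprintf("%s %.8f %.8f %.8f", names, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname writeXyz
#' @return `readXyz` returns a list with `frames` (T x N x 3 array),
#'   `times`, and `names`
#' @export
readXyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric()
  nm <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    times <- c(times, as.numeric(sub(".*time= *([-0-9.eE+]+).*", "\\1",
                                     lines[i + 1])))
    block <- lines[(i + 2):(i + 1 + n)]
    tok <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    nm <- tok[, 1]
    frames[[length(frames) + 1L]] <- matrix(as.numeric(tok[, 2:4]), n, 3)
    i <- i + 2L + n
  }
  arr <- array(NA_real_, c(length(frames), length(nm), 3))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  list(frames = arr, times = times, names = nm)
}

#' Serialize a descriptor matrix as a COLVAR table
#'
#' Layout: `#! FIELDS time <features...> z_dist z_dipole logweight`.
#'
#' @param desc a [DescriptorSet-class]
#' @param path file path
#' @export
writeDescriptors <- function(desc, path) {
  df <- data.frame(time = desc@aux$time, desc@values,
                   z_dist = desc@aux$z_dist, z_dipole = desc@aux$z_dipole,
                   logweight = desc@aux$logweight, check.names = FALSE)
  writeColvar(df, path, meta = list(nBeads = desc@nBeads,
                                    nGroups = desc@nGroups))
}

#' @rdname writeDescriptors
#' @export
readDescriptors <- function(path) {
  df <- readColvar(path)
  meta <- attr(df, "meta")
  auxCols <- c("time", "z_dist", "z_dipole", "logweight")
  feat <- setdiff(colnames(df), auxCols)
  aux <- df[auxCols]
  aux$label <- NA_character_
  new("DescriptorSet", values = as.matrix(df[feat]), aux = aux,
      nBeads = as.integer(meta$nBeads), nGroups = as.integer(meta$nGroups))
}
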