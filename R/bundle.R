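## Self-describing single-file k-space bundle.
## Layout: ASCII magic line "MRFKZBUNDLE <version>\n", a little-endian
## 32-bit header byte length, a JSON header (version, metadata at full
## double precision, and a section table: name, kind, dims, byte offset
## into the payload), then the payload. Array payloads are little-endian
## 32-bit floats (complex data as interleaved real/imaginary pairs,
## documented on-disk precision), 32-bit integers, or single bytes for
## logical masks. The section table makes reading independent of the
## order sections were written in.

BUNDLE_MAGIC <- "MRFKZBUNDLE"
BUNDLE_VERSION <- "1"

section_kind <- function(x) {
  if (is.complex(x)) "c4" else if (is.integer(x)) "i4"
  else if (is.logical(x)) "u1" else "f4"
}

section_bytes <- function(x, kind) {
  switch(kind, c4 = 8L, f4 = 4L, i4 = 4L, u1 = 1L) * length(x)
}

write_section_payload <- function(con, x, kind) {
  switch(kind,
         c4 = writeBin(as.vector(rbind(Re(x), Im(x))), con, size = 4,
                       endian = "little"),
         f4 = writeBin(as.double(x), con, size = 4, endian = "little"),
         i4 = writeBin(as.integer(x), con, size = 4, endian = "little"),
         u1 = writeBin(as.integer(x), con, size = 1))
}

read_section_payload <- function(raw, off, sec) {
  n <- prod(sec$dims)
  at <- off + sec$offset
  out <- switch(sec$kind,
    c4 = {
      v <- readBin(raw[(at + 1):(at + 8 * n)], "double", n = 2 * n, size = 4,
                   endian = "little")
      complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
    },
    f4 = readBin(raw[(at + 1):(at + 4 * n)], "double", n = n, size = 4,
                 endian = "little"),
    i4 = readBin(raw[(at + 1):(at + 4 * n)], "integer", n = n, size = 4,
                 endian = "little"),
    u1 = as.logical(readBin(raw[(at + 1):(at + n)], "integer", n = n,
                            size = 1)))
  if (length(sec$dims) > 1) dim(out) <- sec$dims
  out
}

write_bundle_file <- function(path, sections, meta = list(),
                              section_order = NULL) {
  nm <- names(sections)
  if (is.null(section_order)) section_order <- seq_along(sections)
  table <- list(); off <- 0
  for (k in section_order) {
    x <- sections[[k]]
    kind <- section_kind(x)
    table[[nm[k]]] <- list(name = nm[k], kind = kind,
                           dims = dim(x) %||% length(x), offset = off)
    off <- off + section_bytes(x, kind)
  }
  header <- jsonlite::toJSON(list(version = BUNDLE_VERSION, meta = meta,
                                  sections = table),
                             auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(BUNDLE_MAGIC, " ", BUNDLE_VERSION, "\n")), con)
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  for (k in section_order)
    write_section_payload(con, sections[[k]], section_kind(sections[[k]]))
  invisible(path)
}

read_bundle_file <- function(path) {
  check_that(file.exists(path), "no such bundle file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  fail <- function(...) stop("malformed bundle file: ", ..., call. = FALSE)
  nl <- which(raw == charToRaw("\n"))[1]
  if (is.na(nl)) fail("missing magic line")
  magic <- strsplit(rawToChar(raw[1:(nl - 1)]), " ")[[1]]
  if (magic[1] != BUNDLE_MAGIC) fail("wrong magic")
  if (length(magic) < 2 || magic[2] != BUNDLE_VERSION)
    stop("unsupported bundle version: ", magic[2] %||% "?", call. = FALSE)
  if (length(raw) < nl + 4) fail("truncated header length")
  hlen <- readBin(raw[(nl + 1):(nl + 4)], "integer", size = 4,
                  endian = "little")
  if (length(raw) < nl + 4 + hlen) fail("truncated header")
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(raw[(nl + 5):(nl + 4 + hlen)]),
                       simplifyVector = FALSE),
    error = function(e) fail("unparseable header"))
  off <- nl + 4 + hlen
  sections <- list()
  for (sec in header$sections) {
    sec$dims <- unlist(sec$dims)
    end <- off + sec$offset +
      switch(sec$kind, c4 = 8, f4 = 4, i4 = 4, u1 = 1) * prod(sec$dims)
    if (length(raw) < end) fail("truncated section ", sec$name)
    sections[[sec$name]] <- read_section_payload(raw, off, sec)
  }
  list(meta = header$meta, sections = sections)
}

#' Save an MRF k-space object to a bundle file
#'
#' Serialises the k-space tensor, trajectory, sampling schedule,
#' acquisition schedule and metadata into a single self-describing binary
#' bundle. Array payloads are stored as little-endian 32-bit floats
#' (complex data as interleaved real/imaginary pairs), so a save/load
#' round trip is exact at 32-bit precision; scalar metadata keeps full
#' precision. All stored indices are 0-based.
#'
#' @param path output file path.
#' @param ks an `mrf_kspace` object.
#' @param extra optional named list of additional arrays (e.g. coil maps
#'   or a label volume in synthetic pipelines).
#' @param meta optional named list merged into the metadata block.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(path, ks, extra = list(), meta = list()) {
  check_that(inherits(ks, "mrf_kspace"), "ks must be an mrf_kspace")
  sc <- ks$schedule; tr <- ks$trajectory; acq <- ks$acq
  sections <- c(list(
    kspace = ks$data,
    traj.coords = tr$coords + 0,   # strip dimnames via arithmetic copy
    traj.frame_angles = sc$frame_angles + 0,
    schedule.acs_indices = as.integer(sc$acs_indices),
    schedule.acquired_mask = as.logical(ks$acquired_mask)
  ), extra)
  meta <- c(meta, list(
    R = sc$R, n_partitions = sc$n_partitions, n_acs = sc$n_acs,
    angle_increment = sc$angle_increment,
    k_max = tr$k_max, turns = tr$turns,
    n_interleaves_full = tr$n_interleaves_full,
    n_interleaves = ks$n_interleaves %||% 1L,
    scale = ks$scale %||% 1,
    acq = unclass(acq)))
  write_bundle_file(path, sections, meta)
}

#' Load an MRF k-space object from a bundle file
#'
#' @param path bundle file written by [save_bundle()].
#' @return an `mrf_kspace` object (plus any extra sections attached as
#'   attribute `"extra"`).
#' @export
load_bundle <- function(path) {
  b <- read_bundle_file(path)
  m <- b$meta
  s <- b$sections
  need <- c("kspace", "traj.coords", "traj.frame_angles",
            "schedule.acquired_mask")
  if (!all(need %in% names(s)))
    stop("malformed bundle file: missing sections ",
         paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  traj <- structure(list(coords = s$traj.coords,
                         n_interleaves_full = m$n_interleaves_full,
                         k_max = m$k_max, turns = m$turns),
                    class = "spiral_trajectory")
  Tn <- length(s$traj.frame_angles)
  sched <- structure(list(n_partitions = m$n_partitions, R = m$R,
                          n_acs = m$n_acs,
                          acs_indices = as.integer(s$schedule.acs_indices %||% integer(0)),
                          acquired_indices = which(s$schedule.acquired_mask) - 1L,
                          frame_angles = s$traj.frame_angles,
                          angle_increment = m$angle_increment),
                     class = "sampling_schedule")
  acq <- if (!is.null(m$acq)) {
    a <- lapply(m$acq, function(x) if (is.list(x)) unlist(x) else x)
    a$T <- as.integer(a$T); a$n_segments <- as.integer(a$n_segments)
    a$trs_per_segment <- as.integer(a$trs_per_segment)
    structure(a, class = "acq_schedule")
  }
  ks <- structure(list(data = s$kspace, trajectory = traj, schedule = sched,
                       acq = acq, n_interleaves = m$n_interleaves %||% 1L,
                       acquired_mask = as.logical(s$schedule.acquired_mask),
                       scale = m$scale %||% 1),
                  class = "mrf_kspace")
  extra <- s[setdiff(names(s), need)]
  extra$schedule.acs_indices <- NULL
  if (length(extra)) attr(ks, "extra") <- extra
  ks
}
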