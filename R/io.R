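# Minimal MAT v5 container codec.
#
# Supports exactly what the deposited stimulus/trial layouts need:
# uncompressed little-endian MAT level-5 files holding double-precision
# numeric arrays (any number of dimensions). Everything else (compressed
# elements, cells, structs, non-double classes) raises a named error rather
# than being silently coerced.

MI_INT8 <- 1L
MI_INT32 <- 5L
MI_UINT32 <- 6L
MI_DOUBLE <- 9L
MI_COMPRESSED <- 15L
MI_MATRIX <- 14L
MX_DOUBLE_CLASS <- 6L

#' Write numeric arrays to a MAT v5 file
#'
#' Writes a named list of numeric vectors/matrices/arrays as double-precision
#' variables in an uncompressed little-endian MAT level-5 file, the layout of
#' the deposited stimulus and trial datasets.
#'
#' @param path Output file path.
#' @param vars Named list of numeric arrays (vectors are written as 1 x n).
#' @return `path`, invisibly.
#' @export
write_mat <- function(path, vars) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    stop("all MAT variables must be named", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  # 128-byte header: 116 bytes text, 8 bytes subsystem offset, version, "IM"
  txt <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by streambounce"))
  header <- raw(116)
  header[seq_along(txt)] <- txt
  header[(length(txt) + 1):116] <- as.raw(32L)
  writeBin(header, con)
  writeBin(raw(8), con)
  writeBin(as.raw(c(0x00, 0x01)), con)          # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    writeBin(mat_matrix_element(nm, vars[[nm]]), con)
  }
  invisible(path)
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_pad8 <- function(bytes) {
  extra <- (8 - length(bytes) %% 8) %% 8
  c(bytes, raw(extra))
}

mat_matrix_element <- function(name, x) {
  if (!is.numeric(x)) stop("only numeric variables are supported",
                           call. = FALSE)
  dims <- dim(x)
  if (is.null(dims)) dims <- c(1L, length(x))
  body <- c(
    mat_tag(MI_UINT32, 8L),
    writeBin(as.integer(c(MX_DOUBLE_CLASS, 0L)), raw(), size = 4,
             endian = "little"),
    mat_pad8(c(mat_tag(MI_INT32, 4L * length(dims)),
               writeBin(as.integer(dims), raw(), size = 4,
                        endian = "little"))),
    mat_pad8(c(mat_tag(MI_INT8, nchar(name, type = "bytes")),
               charToRaw(name))),
    mat_pad8(c(mat_tag(MI_DOUBLE, 8L * length(x)),
               writeBin(as.double(x), raw(), size = 8, endian = "little")))
  )
  c(mat_tag(MI_MATRIX, length(body)), body)
}

#' Read numeric arrays from a MAT v5 file
#'
#' Reads all double-precision numeric array variables from an uncompressed
#' little-endian MAT level-5 file. Compressed elements, big-endian files and
#' non-double array classes raise named errors.
#'
#' @param path File path.
#' @return Named list of numeric arrays.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_all <- readBin(path, raw(), n = file.size(path))
  if (length(raw_all) < 128) stop("not a MAT v5 file (truncated header)",
                                  call. = FALSE)
  endian <- rawToChar(raw_all[127:128])
  if (endian == "MI") {
    stop("big-endian MAT files are not supported", call. = FALSE)
  }
  if (endian != "IM") stop("not a MAT v5 file (bad endian indicator)",
                           call. = FALSE)
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw_all)) {
    tag <- parse_mat_tag(raw_all, pos)
    if (tag$type == MI_COMPRESSED) {
      stop("compressed MAT elements are not supported", call. = FALSE)
    }
    if (tag$type != MI_MATRIX) {
      stop("unsupported top-level MAT element type: ", tag$type,
           call. = FALSE)
    }
    v <- parse_mat_matrix(raw_all, tag$data_pos, tag$nbytes)
    out[[v$name]] <- v$value
    pos <- tag$data_pos + tag$nbytes
    pos <- pos + (8 - (pos - 1L) %% 8) %% 8
  }
  out
}

parse_mat_tag <- function(bytes, pos) {
  type <- readBin(bytes[pos:(pos + 3)], integer(), size = 4,
                  endian = "little")
  # small data element: nonzero byte count packed in the upper 16 bits
  small_n <- bitwAnd(bitwShiftR(type, 16L), 0xFFFFL)
  if (small_n > 0L) {
    list(type = bitwAnd(type, 0xFFFFL), nbytes = small_n,
         data_pos = pos + 4L, small = TRUE, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(bytes[(pos + 4):(pos + 7)], integer(), size = 4,
                      endian = "little")
    list(type = type, nbytes = nbytes, data_pos = pos + 8L, small = FALSE,
         next_pos = pos + 8L + nbytes + (8 - nbytes %% 8) %% 8)
  }
}

parse_mat_matrix <- function(bytes, pos, nbytes) {
  end <- pos + nbytes
  flags_tag <- parse_mat_tag(bytes, pos)
  if (flags_tag$type != MI_UINT32 || flags_tag$nbytes != 8L) {
    stop("malformed MAT array flags", call. = FALSE)
  }
  flags <- readBin(bytes[flags_tag$data_pos:(flags_tag$data_pos + 7)],
                   integer(), n = 2, size = 4, endian = "little")
  cls <- bitwAnd(flags[1], 0xFFL)
  if (cls != MX_DOUBLE_CLASS) {
    stop("unsupported MAT array class ", cls,
         " (only double-precision numeric arrays are supported)",
         call. = FALSE)
  }
  pos <- flags_tag$next_pos
  dim_tag <- parse_mat_tag(bytes, pos)
  if (dim_tag$type != MI_INT32) stop("malformed MAT dimensions",
                                     call. = FALSE)
  dims <- readBin(bytes[dim_tag$data_pos:(dim_tag$data_pos +
                                            dim_tag$nbytes - 1)],
                  integer(), n = dim_tag$nbytes / 4L, size = 4,
                  endian = "little")
  pos <- dim_tag$next_pos
  name_tag <- parse_mat_tag(bytes, pos)
  if (name_tag$type != MI_INT8) stop("malformed MAT array name",
                                     call. = FALSE)
  name <- rawToChar(bytes[name_tag$data_pos:(name_tag$data_pos +
                                               name_tag$nbytes - 1)])
  pos <- name_tag$next_pos
  data_tag <- parse_mat_tag(bytes, pos)
  if (data_tag$type != MI_DOUBLE) {
    stop("unsupported MAT data storage type ", data_tag$type,
         " for variable '", name, "' (expected miDOUBLE)", call. = FALSE)
  }
  n <- data_tag$nbytes / 8L
  value <- readBin(bytes[data_tag$data_pos:(data_tag$data_pos +
                                              data_tag$nbytes - 1)],
                   double(), n = n, size = 8, endian = "little")
  if (prod(dims) != n) stop("MAT dimensions do not match data length",
                            call. = FALSE)
  if (length(dims) > 1L && !(length(dims) == 2L && dims[1] == 1L)) {
    dim(value) <- dims
  }
  if (data_tag$next_pos < end) {
    # imaginary part or trailing subelements are out of scope
    stop("complex MAT variables are not supported", call. = FALSE)
  }
  list(name = name, value = value)
}

#' Read a deposited stimulus dataset
#'
#' Loads the 3-D stimulus array (frames x positions x trials, cd/m^2) from a
#' MAT v5 file. The file must contain exactly one 3-D numeric variable; row 1
#' of each layer is the first frame, column 1 the leftmost position, and
#' layer i corresponds to row i of the trial table.
#'
#' @param path MAT file path.
#' @return The 3-D array.
#' @export
read_stimulus_dataset <- function(path) {
  vars <- read_mat(path)
  is3d <- vapply(vars, function(v) length(dim(v)) == 3L, logical(1))
  if (sum(is3d) == 0L) {
    ranks <- vapply(vars, function(v) length(dim(v)), integer(1))
    stop("no 3-D stimulus variable found (expected rank 3, found rank ",
         paste(ranks, collapse = ", "), ")", call. = FALSE)
  }
  if (sum(is3d) > 1L) {
    stop("multiple 3-D candidate variables: ",
         paste(names(vars)[is3d], collapse = ", "), call. = FALSE)
  }
  vars[[which(is3d)]]
}

#' Write a stimulus dataset
#'
#' @param path Output MAT file path.
#' @param stimuli 3-D array (frames x positions x trials).
#' @param name Variable name in the file.
#' @return `path`, invisibly.
#' @export
write_stimulus_dataset <- function(path, stimuli, name = "stimuli") {
  if (length(dim(stimuli)) != 3L) {
    stop("stimuli must be a 3-D array (frames x positions x trials)",
         call. = FALSE)
  }
  vars <- list(unclass(stimuli))
  attributes(vars[[1]]) <- list(dim = dim(stimuli))
  names(vars) <- name
  write_mat(path, vars)
}

TRIAL_COLUMNS <- c("observer", "sound", "previous_response", "block_order",
                   "response", "reaction_time")

#' Read a deposited trial table
#'
#' Loads the per-trial data matrix from a MAT v5 file: a 6-column numeric
#' matrix with columns (observer id, sound presence, previous response,
#' within-block order, response, reaction time in seconds); 1 codes bounce /
#' sound present. Binary columns are validated. A `block` id column is
#' reconstructed from drops in the within-block order, and first-of-block
#' trials (absent from the deposited layout by construction) would be
#' flagged `excluded`.
#'
#' @param path MAT file path.
#' @return A data.frame with the named columns plus `block` and `excluded`.
#' @export
read_trial_table <- function(path) {
  vars <- read_mat(path)
  is2d <- vapply(vars, function(v) length(dim(v)) == 2L, logical(1))
  if (sum(is2d) != 1L) {
    stop("expected exactly one 2-D trial matrix, found ", sum(is2d),
         call. = FALSE)
  }
  m <- vars[[which(is2d)]]
  if (ncol(m) != 6L) {
    stop("trial matrix must have 6 columns, found ", ncol(m), call. = FALSE)
  }
  trials <- as.data.frame(m)
  names(trials) <- TRIAL_COLUMNS
  for (col in c("sound", "previous_response", "response")) {
    if (!all(trials[[col]] %in% c(0, 1))) {
      stop("column '", col, "' must be binary (0/1)", call. = FALSE)
    }
  }
  derive_blocks(trials)
}

# reconstruct block ids from the within-block trial order (a new block starts
# whenever the order fails to increase), separately per observer
derive_blocks <- function(trials) {
  block <- integer(nrow(trials))
  cur <- 0L
  last_obs <- NA
  last_ord <- Inf
  for (i in seq_len(nrow(trials))) {
    if (!identical(trials$observer[i], last_obs) ||
        trials$block_order[i] <= last_ord) {
      cur <- cur + 1L
    }
    block[i] <- cur
    last_obs <- trials$observer[i]
    last_ord <- trials$block_order[i]
  }
  trials$block <- block
  trials$excluded <- trials$block_order == 1
  trials
}

#' Write a trial table in the deposited 6-column layout
#'
#' @param path Output MAT file path.
#' @param trials Trial table with the six canonical columns.
#' @param name Variable name in the file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(path, trials, name = "data") {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0) {
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(trials[, TRIAL_COLUMNS])
  dimnames(m) <- NULL
  vars <- list(m)
  names(vars) <- name
  write_mat(path, vars)
}

#' Load a stimulus + trial dataset bundle
#'
#' Reads the stimulus array and trial table together, checks that stimulus
#' layers and trial rows align, and records provenance (paths, md5
#' checksums).
#'
#' @param stimulus_path,trial_path MAT file paths.
#' @return List with `stimuli`, `trials` and `provenance`.
#' @export
read_dataset_bundle <- function(stimulus_path, trial_path) {
  stimuli <- read_stimulus_dataset(stimulus_path)
  trials <- read_trial_table(trial_path)
  if (dim(stimuli)[3] != nrow(trials)) {
    stop("stimulus layers (", dim(stimuli)[3],
         ") do not match trial rows (", nrow(trials), ")", call. = FALSE)
  }
  list(stimuli = stimuli, trials = trials,
       provenance = list(
         stimulus_path = stimulus_path, trial_path = trial_path,
         stimulus_md5 = unname(tools::md5sum(stimulus_path)),
         trial_md5 = unname(tools::md5sum(trial_path)),
         alignment = "stimulus layer i corresponds to trial row i"))
}

#' Write a kernel matrix as tab-separated text
#'
#' @param path Output path.
#' @param K Kernel matrix (rows = frames, columns = positions).
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(path, K) {
  utils::write.table(K, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a kernel matrix from tab-separated text
#'
#' @param path Input path.
#' @return A numeric matrix.
#' @export
read_kernel_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
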