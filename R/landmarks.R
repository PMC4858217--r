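#' Standard petal-apex landmark roles
#'
#' The five-landmark corolla scheme places one landmark at the apex of each
#' petal. Roles are ordered left-to-right across the flower as seen head-on:
#' left dorsal, left lateral, ventral, right lateral, right dorsal. The
#' dorsal midline (the side with the dorsal slit of the corolla tube) lies
#' between \code{D_left} and \code{D_right}.
#'
#' @return Character vector of the five role labels, in canonical order.
#' @export
standard_roles <- function() {
  c("D_left", "L_left", "V", "L_right", "D_right")
}

#' Assemble a landmark dataset
#'
#' Bundles per-specimen 2-D landmark configurations with specimen and
#' species identifiers plus an optional species metadata table into the
#' container used by all downstream analyses.
#'
#' @param coords numeric array of dimension \code{k x 2 x n} (landmarks,
#'   x/y, specimens), or a list of \code{k x 2} matrices.
#' @param specimen_id character vector of length \code{n}; defaults to a
#'   running index.
#' @param species_id character vector of length \code{n}; defaults to
#'   \code{"unknown"}.
#' @param roles character vector of length \code{k} of landmark role labels;
#'   defaults to [standard_roles()] when \code{k = 5}.
#' @param species optional species metadata \code{data.frame} as returned by
#'   [read_species_table()]; when \code{NULL} a minimal table is derived
#'   from \code{species_id}.
#' @return An object of class \code{"landmark_dataset"}: a list with
#'   elements \code{coords} (k x 2 x n array), \code{specimen_id},
#'   \code{species_id}, \code{roles} and \code{species}.
#' @export
landmark_dataset <- function(coords, specimen_id = NULL, species_id = NULL,
                             roles = NULL, species = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    coords <- array(unlist(coords), dim = c(k, 2L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (is.null(specimen_id)) specimen_id <- sprintf("spec_%03d", seq_len(n))
  if (is.null(species_id)) species_id <- rep("unknown", n)
  if (is.null(roles)) {
    roles <- if (k == 5L) standard_roles() else sprintf("LM%d", seq_len(k))
  }
  stopifnot(length(specimen_id) == n, length(species_id) == n,
            length(roles) == k)
  dimnames(coords) <- list(roles, c("x", "y"), specimen_id)
  if (is.null(species)) {
    tab <- table(species_id)
    species <- data.frame(species_id = names(tab),
                          clade = "outgroup",
                          subjective_label = "unknown",
                          corolla_length = NA_real_,
                          n_images = as.integer(tab),
                          stringsAsFactors = FALSE)
  }
  structure(list(coords = coords,
                 specimen_id = as.character(specimen_id),
                 species_id = as.character(species_id),
                 roles = roles, species = species),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", dim(x$coords)[3], "configurations,",
      dim(x$coords)[1], "landmarks,",
      length(unique(x$species_id)), "species\n")
  cat("Roles:", paste(x$roles, collapse = ", "), "\n")
  invisible(x)
}

#' Number of specimens in a landmark dataset
#' @param d a \code{landmark_dataset}.
#' @return integer count of configurations.
#' @export
n_specimens <- function(d) dim(d$coords)[3]

#' Read a TPS landmark file
#'
#' Parses the tpsDIG dialect: records start with \code{LM=k} followed by
#' \code{k} lines of \code{x y} coordinates; \code{IMAGE=}, \code{ID=} and
#' \code{SCALE=} keys are honoured and unknown keys are skipped with a
#' warning. When \code{SCALE=} is present the record's coordinates are
#' multiplied by the scale factor. Specimen identifiers come from
#' \code{ID=}, else \code{IMAGE=}, else a running index.
#'
#' @param source path to a TPS file, or a character vector of lines.
#' @param roles landmark role labels (length k); default as in
#'   [landmark_dataset()].
#' @param species_id optional per-record species assignment (recycled).
#' @return A \code{landmark_dataset} (configurations only; species table is
#'   the derived minimal one).
#' @export
read_tps <- function(source, roles = NULL, species_id = NULL) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines_trim <- trimws(lines)
  configs <- list()
  ids <- character()
  i <- 1L
  rec <- 0L
  n_lines <- length(lines_trim)
  while (i <= n_lines) {
    ln <- lines_trim[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      stop("TPS parse error at line ", i, ": expected 'LM=' record header, got '",
           ln, "'")
    }
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L) {
      stop("TPS parse error in record ", rec, " at line ", i,
           ": malformed LM count")
    }
    i <- i + 1L
    xy <- matrix(NA_real_, k, 2L)
    got <- 0L
    image <- NA_character_; id <- NA_character_; scale <- NA_real_
    while (i <= n_lines && !grepl("^LM\\s*=", lines_trim[i],
                                  ignore.case = TRUE)) {
      ln <- lines_trim[i]
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*=", ln)) {
        key <- toupper(trimws(sub("=.*$", "", ln)))
        val <- trimws(sub("^[^=]*=", "", ln))
        if (key == "IMAGE") image <- val
        else if (key == "ID") id <- val
        else if (key == "SCALE") {
          scale <- suppressWarnings(as.numeric(val))
          if (is.na(scale)) {
            stop("TPS parse error in record ", rec, " at line ", i,
                 ": non-numeric SCALE")
          }
        } else {
          warning("TPS record ", rec, ": ignoring unknown key '", key, "'")
        }
        i <- i + 1L
        next
      }
      if (got >= k) {
        stop("TPS parse error in record ", rec, ": more than LM=", k,
             " coordinate lines")
      }
      parts <- strsplit(ln, "[\\s,]+", perl = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals)) {
        stop("TPS parse error at line ", i, " (record ", rec,
             "): non-numeric or malformed coordinate line '", ln, "'")
      }
      got <- got + 1L
      xy[got, ] <- vals
      i <- i + 1L
    }
    if (got != k) {
      stop("TPS parse error in record ", rec, ": LM=", k, " but only ", got,
           " coordinate lines found")
    }
    if (!is.na(scale)) xy <- xy * scale
    configs[[rec]] <- xy
    ids[rec] <- if (!is.na(id) && nzchar(id)) id
                else if (!is.na(image) && nzchar(image)) image
                else as.character(rec)
  }
  if (rec == 0L) stop("TPS parse error: no records found")
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L) {
    stop("TPS records disagree on landmark count: ",
         paste(unique(ks), collapse = ", "))
  }
  if (!is.null(species_id)) species_id <- rep_len(species_id, rec)
  landmark_dataset(configs, specimen_id = ids, species_id = species_id,
                   roles = roles)
}

#' Write a TPS landmark file
#'
#' Inverse of [read_tps()] for SCALE-free records: coordinates are written
#' with full double precision so a write/read round trip is exact.
#'
#' @param d a \code{landmark_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tps <- function(d, path) {
  k <- dim(d$coords)[1]
  out <- character()
  for (i in seq_len(n_specimens(d))) {
    out <- c(out, sprintf("LM=%d", k),
             apply(d$coords[, , i, drop = FALSE], 1,
                   function(p) paste(format(p, digits = 17, trim = TRUE,
                                            scientific = FALSE),
                                     collapse = " ")),
             sprintf("ID=%s", d$specimen_id[i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read landmarks from a delimited table
#'
#' Expects columns \code{specimen_id}, \code{species_id}, then coordinate
#' pairs \code{x1,y1,...,xk,yk}. The \code{roles} argument declares the role
#' of each landmark in file order; when the declared roles are a permutation
#' of [standard_roles()] the configuration is reordered to canonical order,
#' so any input landmark ordering can be imported.
#'
#' @param path file path (tab- or comma-delimited; sniffed from the header).
#' @param roles role labels of the landmark columns, in file order.
#' @param species optional species metadata table to attach.
#' @return A \code{landmark_dataset}.
#' @export
read_landmark_table <- function(path, roles = NULL, species = NULL) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cc <- setdiff(names(tab), c("specimen_id", "species_id"))
  if (!all(c("specimen_id", "species_id") %in% names(tab))) {
    stop("landmark table must contain columns 'specimen_id' and 'species_id'")
  }
  if (length(cc) %% 2L != 0L) stop("odd number of coordinate columns")
  k <- length(cc) %/% 2L
  m <- as.matrix(tab[, cc])
  if (!is.numeric(m)) stop("non-numeric coordinate values in landmark table")
  n <- nrow(tab)
  coords <- array(NA_real_, c(k, 2L, n))
  coords[, 1L, ] <- t(m[, seq(1L, 2L * k, by = 2L), drop = FALSE])
  coords[, 2L, ] <- t(m[, seq(2L, 2L * k, by = 2L), drop = FALSE])
  if (is.null(roles) && k == 5L) roles <- standard_roles()
  if (!is.null(roles) && k == 5L && setequal(roles, standard_roles()) &&
      !identical(roles, standard_roles())) {
    perm <- match(standard_roles(), roles)
    coords <- coords[perm, , , drop = FALSE]
    roles <- standard_roles()
  }
  landmark_dataset(coords, specimen_id = as.character(tab$specimen_id),
                   species_id = as.character(tab$species_id),
                   roles = roles, species = species)
}

#' Write landmarks to a delimited table
#' @param d a \code{landmark_dataset}.
#' @param path output path; tab-delimited.
#' @return \code{path}, invisibly.
#' @export
write_landmark_table <- function(d, path) {
  k <- dim(d$coords)[1]
  n <- n_specimens(d)
  m <- matrix(NA_real_, n, 2L * k)
  m[, seq(1L, 2L * k, by = 2L)] <- t(d$coords[, 1L, ])
  m[, seq(2L, 2L * k, by = 2L)] <- t(d$coords[, 2L, ])
  colnames(m) <- as.vector(rbind(paste0("x", seq_len(k)),
                                 paste0("y", seq_len(k))))
  out <- data.frame(specimen_id = d$specimen_id, species_id = d$species_id,
                    m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_label <- function(x, vocabulary) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ -]", "_", y)
  y[!(y %in% vocabulary)] <- "unknown"
  y
}

#' Read a species metadata table
#'
#' Columns \code{species_id}, \code{clade} and \code{subjective_label} are
#' required; \code{corolla_length} (mm) and \code{n_images} are optional.
#' Label vocabulary is normalized case-insensitively ("Bilabiate",
#' "pseudo-radial" etc.); labels outside \{fan, bilabiate, pseudo_radial\}
#' become \code{"unknown"}.
#'
#' @param path file path (tab- or comma-delimited), or a \code{data.frame}.
#' @return \code{data.frame} with columns \code{species_id}, \code{clade},
#'   \code{subjective_label}, \code{corolla_length}, \code{n_images}.
#' @export
read_species_table <- function(path) {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "\"")
  }
  need <- c("species_id", "clade", "subjective_label")
  if (!all(need %in% names(tab))) {
    stop("species table must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$species_id)) {
    stop("duplicate species_id in species table: ",
         paste(unique(tab$species_id[duplicated(tab$species_id)]),
               collapse = ", "))
  }
  cl <- if ("corolla_length" %in% names(tab)) tab$corolla_length else NA
  cl_num <- suppressWarnings(as.numeric(cl))
  bad <- !is.na(cl) & cl != "" & is.na(cl_num)
  if (any(bad)) {
    stop("unparseable corolla_length for species: ",
         paste(tab$species_id[bad], collapse = ", "))
  }
  data.frame(
    species_id = as.character(tab$species_id),
    clade = normalize_label(tab$clade,
                            c("goodenia_sl", "scaevola_sl", "outgroup")),
    subjective_label = normalize_label(tab$subjective_label,
                                       c("fan", "bilabiate", "pseudo_radial")),
    corolla_length = cl_num,
    n_images = if ("n_images" %in% names(tab)) as.integer(tab$n_images)
               else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Validate a landmark dataset
#'
#' Checks the container invariants and returns violations as data, not
#' errors: landmark count at least 3, finite coordinates, unique roles,
#' shared landmark count and role order, every configuration's species
#' resolving to exactly one species record, and species image counts
#' matching the configurations.
#'
#' @param d a \code{landmark_dataset}.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_dataset <- function(d) {
  v <- character()
  k <- dim(d$coords)[1]
  if (k < 3L) v <- c(v, sprintf("dataset: landmark count k = %d < 3", k))
  if (anyDuplicated(d$roles)) {
    v <- c(v, "dataset: duplicated landmark role labels")
  }
  for (i in seq_len(n_specimens(d))) {
    if (!all(is.finite(d$coords[, , i]))) {
      v <- c(v, sprintf("specimen %s: non-finite coordinates",
                        d$specimen_id[i]))
    }
  }
  counts <- table(factor(d$species_id, levels = d$species$species_id))
  orphan <- setdiff(unique(d$species_id), d$species$species_id)
  for (sp in orphan) {
    v <- c(v, sprintf("species %s: configurations present but no species record",
                      sp))
  }
  if (!anyNA(d$species$n_images)) {
    mism <- d$species$species_id[d$species$n_images !=
                                   as.integer(counts[d$species$species_id])]
    for (sp in mism) {
      v <- c(v, sprintf("species %s: n_images does not match configuration count",
                        sp))
    }
  }
  v
}

#' Species-level summary table of the Core Goodeniaceae study
#'
#' Returns the published species-level table for the 44 Core Goodeniaceae
#' species plus the outgroup \emph{Dampiera lindleyi}: clade membership,
#' subjective symmetry label, image counts, mean PC1/PC2 scores, mean
#' numeric cluster code and majority k-means morphotype. Useful as a worked
#' example and as the reference for desk checks of the species-summary
#' arithmetic (counts, discordance, clade means).
#'
#' @return \code{data.frame} with one row per species.
#' @export
goodeniaceae_table1 <- function() {
  path <- system.file("extdata", "goodeniaceae_table1.tsv",
                      package = "petalmorph", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "\"")
}

#' Import landmarks from an XLSX workbook
#'
#' Thin adapter over \pkg{readxl} producing the same dataset as
#' [read_landmark_table()]; the sheet must carry the same column layout
#' (\code{specimen_id}, \code{species_id}, \code{x1,y1,...}). Delimited text
#' remains the canonical interchange format.
#'
#' @param path XLSX file path.
#' @param sheet sheet name or index (default first).
#' @param roles,species as in [read_landmark_table()].
#' @return A \code{landmark_dataset}.
#' @export
read_landmark_xlsx <- function(path, sheet = 1, roles = NULL, species = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("read_landmark_xlsx requires the 'readxl' package")
  }
  tab <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_landmark_table(tmp, roles = roles, species = species)
}
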