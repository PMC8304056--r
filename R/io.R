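#' Default residue/atom grouping rules
#'
#' Ordered rules mapping residue and atom names to the structural groups
#' "water", "head" and "tail"; the first matching rule wins and unmatched
#' atoms fall into "other".  Each rule is a list with a `group` and optional
#' regular expressions `resname` and `atom`.
#'
#' @return List of rules, suitable for [read_structure()].
#' @export
default_grouping <- function() {
  list(
    list(group = "water", resname = "^(SOL|HOH|WAT|TIP.?|SPC)$"),
    list(group = "head",
         atom = "^(P|N|O[0-9]*|C1[0-5]?|N[A-Z0-9]*|P[A-Z0-9]*|H[0-9]*[A-Z]?)$",
         resname = "^(DMPC|DLPC|POPC|DPPC|SOPC|LIP)"),
    list(group = "tail", resname = "^(DMPC|DLPC|POPC|DPPC|SOPC|LIP)")
  )
}

apply_grouping <- function(resname, atom, rules) {
  group <- rep("other", length(resname))
  open <- rep(TRUE, length(resname))
  for (rule in rules) {
    hit <- open
    if (!is.null(rule$resname)) hit <- hit & grepl(rule$resname, resname)
    if (!is.null(rule$atom)) hit <- hit & grepl(rule$atom, atom)
    group[hit] <- rule$group
    open <- open & !hit
  }
  group
}

# isotope label from an atom/element name: strip decorating digits, map
# D -> 2H, recognize the common two-letter elements
label_from_atom <- function(atom, element = NULL) {
  src <- trimws(atom)
  if (!is.null(element)) {
    el <- trimws(element)
    src <- ifelse(nzchar(el), el, src)
  }
  lab <- sub("^[0-9]+", "", src)
  lab <- sub("^([A-Za-z]+).*$", "\\1", lab)
  first2 <- paste0(toupper(substr(lab, 1, 1)), tolower(substr(lab, 2, 2)))
  out <- ifelse(first2 %in% c("Cl", "Ca", "Na", "Mg", "Si"),
                first2, toupper(substr(lab, 1, 1)))
  ifelse(out == "D", "2H", out)
}

add_implicit_h <- function(atoms, implicit_h) {
  if (is.null(implicit_h) || length(implicit_h) == 0) return(atoms)
  extra <- list()
  for (pat in names(implicit_h)) {
    k <- implicit_h[[pat]]
    hit <- grepl(pat, atoms$atom_name)
    if (any(hit) && k > 0) {
      dup <- atoms[rep(which(hit), each = k), , drop = FALSE]
      dup$label <- "H"
      extra[[length(extra) + 1L]] <- dup
    }
  }
  if (length(extra)) rbind(atoms, do.call(rbind, extra)) else atoms
}

frame_from_table <- function(tab, box, grouping, implicit_h) {
  tab$label <- label_from_atom(tab$atom_name, tab$element)
  tab$group <- apply_grouping(tab$resname, tab$atom_name, grouping)
  tab <- add_implicit_h(tab, implicit_h)
  md_frame(tab[, c("label", "group", "x", "y", "z")], box)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      stop("malformed GRO atom count at line ", i + 1L)
    if (i + 1L + natoms + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i,
           ": atom records or the box line are missing")
    rec <- lines[(i + 2L):(i + 1L + natoms)]
    resname <- trimws(substr(rec, 6, 10))
    atom <- trimws(substr(rec, 11, 15))
    x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
    if (length(bad))
      stop("malformed GRO coordinate record at line ", i + 1L + bad[1])
    box <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (length(box) < 3 || any(!is.finite(box[1:3])))
      stop("missing or malformed GRO box at line ", i + 2L + natoms)
    frames[[length(frames) + 1L]] <- list(
      tab = data.frame(resname = resname, atom_name = atom, element = "",
                       x = x * 10, y = y * 10, z = z * 10,
                       stringsAsFactors = FALSE),
      box = box[1:3] * 10)   # nm -> Angstrom
    i <- i + 2L + natoms + 1L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  # bio3d does not expose CRYST1; take the cell edges from the record itself
  cryst <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
  box <- if (length(cryst))
    suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                  substr(cryst[1], 16, 24),
                                  substr(cryst[1], 25, 33))))
  else NULL
  if (is.null(box) || length(box) < 3 || any(!is.finite(box)))
    stop("missing CRYST1 box record in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  at <- pdb$atom
  elem <- if ("elesy" %in% names(at)) at$elesy else ""
  lapply(seq_len(nrow(xyz)), function(f) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    list(tab = data.frame(resname = at$resid, atom_name = at$elety,
                          element = elem,
                          x = co[, 1], y = co[, 2], z = co[, 3],
                          stringsAsFactors = FALSE),
         box = box[1:3])
  })
}

#' Read a structure or trajectory file into frames
#'
#' Reads single- or multi-frame PDB (via bio3d; frame count follows the
#' MODEL records) or GROMACS GRO files (fixed-column parser; nm converted
#' to Angstrom), assigns structural groups from residue/atom-name rules and
#' resolves isotope labels from element/atom names (names starting with "D"
#' become deuterium).  United-atom beads can declare implicit hydrogens via
#' `implicit_h`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param grouping Grouping rules, see [default_grouping()].
#' @param implicit_h Optional named vector: atom-name regex -> number of
#'   implicit H added at the bead position.
#' @return List of [md_frame()] objects.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           grouping = default_grouping(),
                           implicit_h = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  raw <- switch(format, gro = read_gro_frames(path), pdb = read_pdb_frames(path))
  lapply(raw, function(fr)
    frame_from_table(fr$tab, fr$box, grouping, implicit_h))
}

#' Write frames as a multi-model PDB file
#'
#' Minimal writer for fixture trajectories: CRYST1 plus MODEL/ATOM/ENDMDL
#' records, Angstrom coordinates, group tag stored as the residue name
#' (HEA/TAI/SOL/OTH) so [read_structure()] round-trips the grouping.
#'
#' @param frames List of [md_frame()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  box <- frames[[1]]$box
  res_of <- c(head = "HEA", tail = "TAI", water = "SOL", other = "OTH")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    box[1], box[2], box[3]), con)
  for (f in seq_along(frames)) {
    at <- frames[[f]]$atoms
    writeLines(sprintf("MODEL     %4d", f), con)
    lab <- sub("^2H$", "D", at$label)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      (seq_len(nrow(at)) - 1L) %% 99999 + 1L, substr(lab, 1, 4),
      res_of[at$group], (seq_len(nrow(at)) - 1L) %% 9999 + 1L,
      at$x, at$y, at$z, substr(lab, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

parse_curve_table <- function(path) {
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no data rows in ", path)
  fields <- strsplit(trimws(data_lines), "[\\s,]+", perl = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1)
    stop("inconsistent column counts in ", path)
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = ncol, byrow = TRUE))
  bad <- which(apply(vals, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-numeric record in ", path, " at data row ", bad[1])
  list(vals = vals, comments = comments)
}

#' Read a measured scattering curve from ASCII columns
#'
#' Parses 3/4-column whitespace- or comma-separated files: Q, intensity,
#' 1-sigma uncertainty and optionally dQ.  Lines starting with `#` are
#' comments and preserved in the `comments` attribute.
#'
#' @param path File path.
#' @param kind `"reflectivity"` (returns [refl_curve()]) or `"sans"`
#'   (returns [sans_curve()]).
#' @return A curve object with uncertainties; 4-column files carry `dQ`.
#' @export
read_curve <- function(path, kind = c("reflectivity", "sans")) {
  kind <- match.arg(kind)
  parsed <- parse_curve_table(path)
  vals <- parsed$vals
  if (ncol(vals) < 3)
    stop("need at least 3 columns (Q, intensity, uncertainty): ", path,
         " has ", ncol(vals), " - the uncertainty column is missing")
  if (any(diff(vals[, 1]) <= 0)) stop("non-monotonic Q in ", path)
  if (any(vals[, 3] < 0)) stop("negative uncertainties in ", path)
  out <- if (kind == "reflectivity")
    refl_curve(vals[, 1], vals[, 2], dR = vals[, 3])
  else sans_curve(vals[, 1], vals[, 2], dI = vals[, 3])
  if (ncol(vals) >= 4) out$dQ <- vals[, 4]
  attr(out, "comments") <- parsed$comments
  out
}

#' Write a scattering curve as ASCII columns
#'
#' @param curve A [refl_curve()] or [sans_curve()].
#' @param path Output path.
#' @param comments Optional character vector written as `#` header lines.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path, comments = NULL) {
  y_field <- if (inherits(curve, "sans_curve")) "I" else "R"
  e_field <- if (y_field == "I") "dI" else "dR"
  header <- c(comments,
              paste("# Q_invA", y_field, e_field,
                    if (!is.null(curve$dQ)) "dQ_invA"))
  err <- curve[[e_field]]
  if (is.null(err)) err <- rep(0, length(curve$Q))
  cols <- cbind(curve$Q, curve[[y_field]], err,
                if (!is.null(curve$dQ)) curve$dQ)
  body <- apply(cols, 1, function(r)
    paste(formatC(r, format = "e", digits = 9), collapse = " "))
  writeLines(c(ifelse(grepl("^#", header), header, paste("#", header)), body),
             path)
  invisible(path)
}

#' Write an SLD profile as TSV
#'
#' Columns: z centre (A), total SLD (1/A^2) and, when present, the
#' per-group contributions; `#` header records bin width and the
#' semi-infinite media so the profile round-trips through
#' [read_profile_tsv()].
#'
#' @param profile An [sld_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  zc <- bin_centers(profile)
  mat <- cbind(z_A = zc, sld = profile$rho)
  if (!is.null(profile$breakdown))
    mat <- cbind(mat, profile$breakdown)
  header <- c(sprintf("# bin_width %.10g", profile$bin_width),
              sprintf("# fronting %.10g", profile$fronting),
              sprintf("# backing %.10g", profile$backing),
              if (!is.null(profile$contrast))
                paste("# contrast", profile$contrast),
              paste("#", paste(colnames(mat), collapse = "\t")))
  body <- apply(mat, 1, function(r)
    paste(formatC(r, format = "e", digits = 10), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an SLD profile written by [write_profile_tsv()]
#'
#' @param path File path.
#' @return An [sld_profile()].
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, " "), lines, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^# ", key, " "), "", hit[1]))
    else NULL
  }
  contrast <- grep("^# contrast ", lines, value = TRUE)
  parsed <- parse_curve_table(path)
  zc <- parsed$vals[, 1]
  rho <- parsed$vals[, 2]
  w <- get_meta("bin_width")
  if (is.null(w)) w <- stats::median(diff(zc))
  # rebuild a strictly uniform grid: printed centres carry rounding noise
  edges <- zc[1] - w / 2 + w * (0:length(zc))
  sld_profile(edges, rho, fronting = get_meta("fronting"),
              backing = get_meta("backing"),
              contrast = if (length(contrast))
                sub("^# contrast ", "", contrast[1]) else NULL)
}

#' Reduced chi-square between a measured and a model curve
#'
#' Interpolates the model onto the data grid (linearly in log10 intensity
#' when both curves are strictly positive, linearly otherwise) and returns
#' sum(((y_data - y_model) / dy)^2) / (N - k).
#'
#' @param data Curve with uncertainties (`dR` or `dI`) > 0.
#' @param model Model curve whose Q range covers the data.
#' @param n_free Number of fitted parameters k.
#' @return Reduced chi-square (single number).
#' @export
chi_square <- function(data, model, n_free = 0) {
  y_field <- if (inherits(data, "sans_curve")) "I" else "R"
  e_field <- if (y_field == "I") "dI" else "dR"
  err <- data[[e_field]]
  if (is.null(err) || any(err <= 0))
    stop("data curve must carry strictly positive uncertainties")
  if (min(data$Q) < min(model$Q) - 1e-12 ||
      max(data$Q) > max(model$Q) + 1e-12)
    stop("model Q range does not cover the data (disjoint or partial grids)")
  ym <- model[[y_field]]
  yd <- data[[y_field]]
  pos <- all(ym > 0)
  mi <- if (pos) 10^stats::approx(model$Q, log10(ym), xout = data$Q,
                                  rule = 2)$y
        else stats::approx(model$Q, ym, xout = data$Q, rule = 2)$y
  dof <- max(length(yd) - n_free, 1L)
  sum(((yd - mi) / err)^2) / dof
}

config_schema <- c("input", "format", "output", "grouping", "implicit_h",
                   "contrasts", "bin_width", "substrate", "multilayer",
                   "instrument", "verbosity", "seed")

#' Read and validate a run configuration
#'
#' YAML configuration binding the pipeline together.  Top-level keys are
#' checked against the documented schema and unknown keys are rejected
#' before any computation.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), config_schema)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(config_schema, collapse = ", "))
  cfg
}
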