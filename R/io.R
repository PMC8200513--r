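#' Read / write a treatment plan (JSON)
#'
#' Canonical plan schema:
#' ```
#' {"machine": {"pivot_cm": 96, "gimbal_deg": 2.4, "iso_plane_cm": 4.2},
#'  "beams": [{"label": "beam1", "iso_cm": [x, y, z], "gantry_deg": 192,
#'             "ring_deg": 17, "collimator_deg": 0, "weight": 1,
#'             "aperture": {"type": "circle", "radius_cm": 2.5}}, ...]}
#' ```
#' Angles are normalized to `[0, 360)` on read; the round trip is lossless at
#' full double precision.
#'
#' @param path File path.
#' @return `read_plan()`: a `beam_plan` tibble with attribute `machine`.
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$beams) || length(doc$beams) == 0L)
    stop("plan JSON at /beams must be a non-empty array", call. = FALSE)
  beams <- purrr::imap_dfr(doc$beams, function(b, i) {
    for (field in c("iso_cm", "gantry_deg", "ring_deg"))
      if (is.null(b[[field]]))
        stop(sprintf("plan JSON missing /beams/%d/%s", i, field),
             call. = FALSE)
    if (length(b$iso_cm) != 3L)
      stop(sprintf("plan JSON /beams/%d/iso_cm must have 3 components", i),
           call. = FALSE)
    tibble::tibble(label = b$label %||% sprintf("beam%d", i),
                   iso_x = b$iso_cm[[1]], iso_y = b$iso_cm[[2]],
                   iso_z = b$iso_cm[[3]],
                   gantry = b$gantry_deg, ring = b$ring_deg,
                   collimator = b$collimator_deg %||% 0,
                   weight = b$weight %||% 1,
                   aperture = list(parse_aperture(b$aperture)))
  })
  mach <- if (is.null(doc$machine)) machine_model() else
    machine_model(pivot_cm = doc$machine$pivot_cm %||% 96,
                  gimbal_deg = doc$machine$gimbal_deg %||% 2.4,
                  iso_plane_cm = doc$machine$iso_plane_cm %||% 4.2)
  plan <- beam_plan(beams$label, beams$iso_x, beams$iso_y, beams$iso_z,
                    beams$gantry, beams$ring, beams$collimator, beams$weight,
                    aperture = beams$aperture)
  if (all(vapply(plan$aperture, is.null, logical(1)))) plan$aperture <- NULL
  attr(plan, "machine") <- mach
  plan
}

parse_aperture <- function(a) {
  if (is.null(a)) return(NULL)
  if (identical(a$type, "circle")) return(aperture_circle(a$radius_cm))
  stop("unsupported aperture type: ", a$type, call. = FALSE)
}

#' @rdname read_plan
#' @param plan A `beam_plan`.
#' @param machine A [machine_model()]; defaults to the plan's `machine`
#'   attribute.
#' @export
write_plan <- function(plan, path, machine = NULL) {
  plan <- as_beam_plan(plan)
  machine <- machine %||% attr(plan, "machine") %||% machine_model()
  beams <- purrr::map(seq_len(nrow(plan)), function(i) {
    b <- list(label = plan$label[i],
              iso_cm = c(plan$iso_x[i], plan$iso_y[i], plan$iso_z[i]),
              gantry_deg = plan$gantry[i], ring_deg = plan$ring[i],
              collimator_deg = plan$collimator[i], weight = plan$weight[i])
    ap <- if (!is.null(plan$aperture)) plan$aperture[[i]] else NULL
    if (!is.null(ap)) b$aperture <- list(type = ap$type,
                                         radius_cm = ap$radius_cm)
    b
  })
  jsonlite::write_json(
    list(machine = list(pivot_cm = machine$pivot_cm,
                        gimbal_deg = machine$gimbal_deg,
                        iso_plane_cm = machine$iso_plane_cm),
         beams = beams),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write fiducial positions per phase (JSON)
#'
#' Schema: `{"phase_label": [[x, y, z], ...], ...}` in cm.
#'
#' @param path File path.
#' @return `read_fiducials()`: a named list of [fiducial_state()] objects.
#' @export
read_fiducials <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc) == 0L) stop("fiducial JSON holds no phases", call. = FALSE)
  purrr::imap(doc, function(m, phase) {
    m <- if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
    fiducial_state(m, phase = phase)
  })
}

#' @rdname read_fiducials
#' @param states Named list of [fiducial_state()] objects.
#' @export
write_fiducials <- function(states, path) {
  out <- purrr::map(states, function(s) unname(as.matrix(s[c("x", "y", "z")])))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Read / write a respiratory trace (CSV)
#'
#' Two-column CSV with header `time_s,amplitude`.
#'
#' @param path File path.
#' @return `read_trace()`: a [breathing_trace()].
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("trace CSV needs columns time_s and amplitude", call. = FALSE)
  breathing_trace(df$time_s, df$amplitude)
}

#' @rdname read_trace
#' @param trace A [breathing_trace()].
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s,
                                  amplitude = trace$amplitude), path)
  invisible(path)
}

#' Read an organ-at-risk constraint table (CSV)
#'
#' Columns `organ,limit_cGy`.
#'
#' @param path File path.
#' @return A tibble with columns `organ`, `limit_cGy`.
#' @export
read_constraints <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("organ", "limit_cGy") %in% names(df)))
    stop("constraints CSV needs columns organ and limit_cGy", call. = FALSE)
  tibble::tibble(organ = as.character(df$organ),
                 limit_cGy = as.numeric(df$limit_cGy))
}

# ---- NRRD ------------------------------------------------------------------
# Minimal NRRD0004 support for 3-D scalar grids and 3-vector fields
# (encodings: raw little-endian doubles, or ascii). No installed R package
# reads NRRD, hence this self-contained implementation.

#' Write a grid or deformation field as NRRD
#'
#' Scalar grids ([dose_grid()] / [roi_mask()]) are written as 3-D `double`
#' NRRD with `space origin` / `space directions`; deformation fields as 4-D
#' with a leading vector axis, `kinds: vector domain domain domain`, and the
#' key `dvf_direction:=reference_to_phase` so the field direction convention
#' travels with the file.
#'
#' @param x A [dose_grid()], [roi_mask()] or [deformation_field()].
#' @param path Output path.
#' @param encoding `"raw"` (little-endian doubles) or `"ascii"`.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_dvf <- inherits(x, "deformation_field")
  vals <- if (is_dvf) aperm(x$u, c(4, 1, 2, 3)) else
    (if (inherits(x, "roi_mask")) array(as.numeric(x$values), dim(x$values))
     else x$values)
  sizes <- if (is_dvf) dim(vals) else dim(vals)
  dirs <- sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                  x$spacing[1], x$spacing[2], x$spacing[3])
  if (is_dvf) dirs <- paste("none", dirs)
  hdr <- c("NRRD0004",
           "type: double",
           sprintf("dimension: %d", length(sizes)),
           sprintf("sizes: %s", paste(sizes, collapse = " ")),
           sprintf("kinds: %s", if (is_dvf) "vector domain domain domain"
                   else "domain domain domain"),
           sprintf("encoding: %s", encoding),
           "endian: little",
           "space dimension: 3",
           sprintf("space origin: (%.9g,%.9g,%.9g)",
                   x$origin[1], x$origin[2], x$origin[3]),
           sprintf("space directions: %s", dirs))
  if (is_dvf) hdr <- c(hdr, "dvf_direction:=reference_to_phase")
  if (inherits(x, "roi_mask")) hdr <- c(hdr, sprintf("roi_name:=%s", x$name))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(vals), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an NRRD grid or deformation field
#'
#' @param path NRRD file written by [write_nrrd()] (or any NRRD restricted to
#'   the supported subset: `type double/float/int/...`, 3-D scalar or
#'   vector-first 4-D, raw or ascii encoding).
#' @param as For 3-D data: return a `"dose_grid"` (default) or `"roi_mask"`.
#' @return A [dose_grid()], [roi_mask()] or [deformation_field()].
#' @export
read_nrrd <- function(path, as = c("dose_grid", "roi_mask")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list(); keys <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keys[[kv[1]]] <- kv[2]
    } else {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(kv[1])]] <- kv[2]
    }
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  ndim <- as.integer(fields$dimension)
  encoding <- trimws(fields$encoding)
  type <- trimws(fields$type)
  n <- prod(sizes)
  vals <- if (encoding == "raw") {
    size <- switch(type, double = 8L, float = 4L,
                   int = 4L, `signed int` = 4L, `unsigned char` = 1L,
                   short = 2L, stop("unsupported NRRD type: ", type))
    what <- if (type %in% c("double", "float")) numeric() else integer()
    as.numeric(readBin(con, what, n = n, size = size, endian = "little",
                       signed = size > 1L))
  } else if (encoding %in% c("ascii", "txt", "text")) {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  origin <- parse_nrrd_vector(fields[["space origin"]]) %||% c(0, 0, 0)
  sdirs <- fields[["space directions"]]
  spacing <- if (is.null(sdirs)) c(1, 1, 1) else {
    toks <- regmatches(sdirs, gregexpr("\\(([^)]*)\\)", sdirs))[[1]]
    vecs <- lapply(toks, function(t)
      as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]]))
    vapply(seq_along(vecs), function(i) sqrt(sum(vecs[[i]]^2)), numeric(1))
  }
  if (ndim == 4L) {
    if (sizes[1] != 3L)
      stop("only vector-first 4-D NRRD (sizes 3 nx ny nz) is supported",
           call. = FALSE)
    u <- aperm(array(vals, sizes), c(2, 3, 4, 1))
    return(deformation_field(u, origin = origin, spacing = spacing))
  }
  arr <- array(vals, sizes)
  if (as == "roi_mask")
    roi_mask(arr != 0, origin = origin, spacing = spacing,
             name = keys$roi_name %||% sub("\\.nrrd$", "", basename(path)))
  else dose_grid(pmax(arr, 0), origin = origin, spacing = spacing)
}

parse_nrrd_vector <- function(s) {
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(gsub("[()]", "", trimws(s)), ",")[[1]])
}

#' Read / write a grid as NIfTI (experimental)
#'
#' Thin adapters over \pkg{RNifti}. The grid spacing is carried in `pixdim`
#' and the origin in the sform translation; values are centimetres
#' reinterpreted as the NIfTI spatial unit. Deformation fields are not
#' supported through this path.
#'
#' @param x A [dose_grid()].
#' @param path File path (`.nii` / `.nii.gz`).
#' @export
write_nifti_grid <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package", call. = FALSE)
  stopifnot(inherits(x, "dose_grid"))
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  img <- RNifti::asNifti(x$values)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package", call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- vapply(1:3, function(i) sqrt(sum(aff[1:3, i]^2)), numeric(1))
  dose_grid(pmax(array(as.numeric(img), dim(img)[1:3]), 0),
            origin = aff[1:3, 4], spacing = spacing)
}
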