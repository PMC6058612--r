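# imzML 1.1 I/O: XML part via xml2, external binary (.ibd) via readBin/
# writeBin. Both continuous mode (shared m/z axis) and processed mode
# (per-pixel axes) are supported; all arrays are 64-bit little-endian floats.
# The ibd UUID and SHA-1 checksum recorded in the XML are honored on read.

ibd_path_for <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

fmt_uuid <- function(raw16) {
  h <- paste(format(raw16), collapse = "")
  paste0(substr(h, 1, 8), "-", substr(h, 9, 12), "-", substr(h, 13, 16), "-",
         substr(h, 17, 20), "-", substr(h, 21, 32))
}

cvp <- function(cv, acc, name, value = NULL, unit = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  u <- if (is.null(unit)) "" else
    sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
            unit[1], unit[2])
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
          cv, acc, name, v, u)
}

#' Write an MSI dataset as imzML + ibd
#'
#' Produces a standards-conforming imzML 1.1 file pair: an XML index and the
#' external binary data file with a shared UUID and a SHA-1 checksum of the
#' binary file. Intensities and m/z values are stored as 64-bit floats, so
#' `read_imzml(write_imzml(x))` reproduces coordinates exactly and spectra
#' bit-exactly.
#'
#' @param x an `msi_dataset`.
#' @param path output path ending in `.imzML`; the `.ibd` companion is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(x, path) {
  validate_msi_dataset(x)
  ibd <- ibd_path_for(path)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  n <- n_pixels(x)

  con <- file(ibd, "wb")
  ok <- FALSE
  tryCatch({
    writeBin(uuid, con)
    offset <- 16
    if (x$mode == "continuous") {
      p <- length(x$mz)
      writeBin(as.numeric(x$mz), con, size = 8, endian = "little")
      mz_off <- rep(16, n); mz_len <- rep(p, n)
      offset <- offset + 8 * p
      int_off <- integer(n); int_len <- rep(p, n)
      for (i in seq_len(n)) {
        int_off[i] <- offset
        writeBin(as.numeric(x$intensities[i, ]), con, size = 8,
                 endian = "little")
        offset <- offset + 8 * p
      }
    } else {
      mz_off <- int_off <- numeric(n)
      mz_len <- int_len <- lengths(x$mz)
      for (i in seq_len(n)) {
        mz_off[i] <- offset
        writeBin(as.numeric(x$mz[[i]]), con, size = 8, endian = "little")
        offset <- offset + 8 * mz_len[i]
        int_off[i] <- offset
        writeBin(as.numeric(x$intensities[[i]]), con, size = 8,
                 endian = "little")
        offset <- offset + 8 * int_len[i]
      }
    }
    ok <- TRUE
  }, finally = close(con))
  if (!ok) stop("failed writing ibd: ", ibd)
  sha1 <- digest::digest(file = ibd, algo = "sha1")

  mode_acc <- if (x$mode == "continuous")
    cvp("IMS", "IMS:1000030", "continuous")
  else cvp("IMS", "IMS:1000031", "processed")
  pol_acc <- if (x$polarity == "positive")
    cvp("MS", "MS:1000130", "positive scan")
  else cvp("MS", "MS:1000129", "negative scan")

  spectra <- character(n)
  for (i in seq_len(n)) {
    spectra[i] <- paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i,
      '" defaultArrayLength="', mz_len[i], '">', pol_acc,
      '<scanList count="1">',
      cvp("MS", "MS:1000795", "no combination"),
      "<scan>",
      cvp("IMS", "IMS:1000050", "position x", x$coords[i, 1]),
      cvp("IMS", "IMS:1000051", "position y", x$coords[i, 2]),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cvp("IMS", "IMS:1000102", "external offset", mz_off[i]),
      cvp("IMS", "IMS:1000103", "external array length", mz_len[i]),
      cvp("IMS", "IMS:1000104", "external encoded length", 8 * mz_len[i]),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cvp("IMS", "IMS:1000102", "external offset", int_off[i]),
      cvp("IMS", "IMS:1000103", "external array length", int_len[i]),
      cvp("IMS", "IMS:1000104", "external encoded length", 8 * int_len[i]),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    mode_acc,
    cvp("IMS", "IMS:1000080", "universally unique identifier",
        paste0("{", fmt_uuid(uuid), "}")),
    cvp("IMS", "IMS:1000091", "ibd SHA-1", sha1),
    cvp("MS", "MS:1000294", "mass spectrum"),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cvp("MS", "MS:1000514", "m/z array", unit = c("MS:1000040", "m/z")),
    cvp("MS", "MS:1000523", "64-bit float"),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cvp("MS", "MS:1000515", "intensity array",
        unit = c("MS:1000131", "number of detector counts")),
    cvp("MS", "MS:1000523", "64-bit float"),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    cvp("IMS", "IMS:1000042", "max count of pixels x", max(x$coords[, 1])),
    cvp("IMS", "IMS:1000043", "max count of pixels y", max(x$coords[, 2])),
    cvp("IMS", "IMS:1000046", "pixel size (x)", x$pixel_size,
        unit = c("UO:0000017", "micrometer")),
    cvp("IMS", "IMS:1000047", "pixel size y", x$pixel_size,
        unit = c("UO:0000017", "micrometer")),
    sprintf('<userParam name="mz_range_lo" value="%.17g"/>', x$mz_range[1]),
    sprintf('<userParam name="mz_range_hi" value="%.17g"/>', x$mz_range[2]),
    "</scanSettings></scanSettingsList>",
    '<softwareList count="1"><software id="lungtarget" version="0.1">',
    cvp("MS", "MS:1000799", "custom unreleased software tool", "lungtarget"),
    "</software></softwareList>",
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1">',
    cvp("MS", "MS:1000031", "instrument model"),
    "</instrumentConfiguration></instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="lungtarget">',
    cvp("MS", "MS:1000544", "Conversion to mzML"),
    "</processingMethod></dataProcessing></dataProcessingList>",
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="none">', n),
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Read an imzML + ibd file pair
#'
#' Parses the XML index, verifies the ibd SHA-1 checksum recorded there, and
#' loads every pixel's spectrum. Continuous and processed binary modes are
#' both handled; nothing is dropped silently.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @param check_checksum verify the ibd SHA-1 against the recorded value
#'   (default `TRUE`).
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path, check_checksum = TRUE) {
  if (!file.exists(path)) stop("no such imzML file: ", path)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) stop("missing ibd companion: ", ibd)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  acc <- function(node, a)
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf('.//cvParam[@accession="%s"]', a)), "value")
  has_acc <- function(node, a)
    !is.na(xml2::xml_attr(xml2::xml_find_first(
      node, sprintf('.//cvParam[@accession="%s"]', a)), "accession"))

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  mode <- if (has_acc(fc, "IMS:1000030")) "continuous"
          else if (has_acc(fc, "IMS:1000031")) "processed"
          else stop("file declares neither continuous nor processed mode")
  sha_recorded <- acc(fc, "IMS:1000091")
  if (check_checksum && !is.na(sha_recorded)) {
    sha_actual <- digest::digest(file = ibd, algo = "sha1")
    if (tolower(sha_recorded) != tolower(sha_actual))
      stop("ibd SHA-1 checksum mismatch: recorded ", sha_recorded,
           ", actual ", sha_actual)
  }

  for (grp_id in c("mzArray", "intensityArray")) {
    grp <- xml2::xml_find_first(
      doc, sprintf('.//referenceableParamGroup[@id="%s"]', grp_id))
    if (!has_acc(grp, "MS:1000523"))
      stop("only 64-bit float arrays are supported (group ", grp_id, ")")
  }

  mz_groups <- xml2::xml_find_all(doc, './/referenceableParamGroup')
  mz_id <- "mzArray"; int_id <- "intensityArray"
  for (g in mz_groups) {
    if (has_acc(g, "MS:1000514")) mz_id <- xml2::xml_attr(g, "id")
    if (has_acc(g, "MS:1000515")) int_id <- xml2::xml_attr(g, "id")
  }

  px <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, './/scanSettings/cvParam[@accession="IMS:1000046"]'), "value"))
  if (is.na(px)) px <- 1
  up <- function(nm) as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, sprintf('.//userParam[@name="%s"]', nm)), "value"))

  spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  n <- length(spectra)
  if (n == 0L) stop("empty dataset: imzML file contains no spectra")

  coords <- matrix(0L, n, 2, dimnames = list(NULL, c("x", "y")))
  mz_off <- int_off <- mz_len <- int_len <- numeric(n)
  polarity <- "positive"
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    if (has_acc(sp, "MS:1000129")) polarity <- "negative"
    scan <- xml2::xml_find_first(sp, ".//scanList/scan")
    coords[i, ] <- c(as.integer(acc(scan, "IMS:1000050")),
                     as.integer(acc(scan, "IMS:1000051")))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "referenceableParamGroupRef"), "ref")
      off <- as.numeric(acc(bda, "IMS:1000102"))
      len <- as.numeric(acc(bda, "IMS:1000103"))
      if (identical(ref, mz_id)) { mz_off[i] <- off; mz_len[i] <- len }
      else if (identical(ref, int_id)) { int_off[i] <- off; int_len[i] <- len }
    }
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_arr <- function(off, len) {
    seek(con, where = off, origin = "start")
    readBin(con, "numeric", n = len, size = 8, endian = "little")
  }

  if (mode == "continuous") {
    mz <- read_arr(mz_off[1], mz_len[1])
    ints <- matrix(0, n, length(mz))
    for (i in seq_len(n)) ints[i, ] <- read_arr(int_off[i], int_len[i])
    if (any(ints < 0)) stop("negative intensities in ibd")
    mz_range <- c(up("mz_range_lo"), up("mz_range_hi"))
    if (anyNA(mz_range)) mz_range <- range(mz)
    msi_dataset(coords, mz, ints, mode = "continuous", pixel_size = px,
                polarity = polarity, mz_range = mz_range)
  } else {
    mzl <- vector("list", n); intl <- vector("list", n)
    for (i in seq_len(n)) {
      mzl[[i]] <- read_arr(mz_off[i], mz_len[i])
      intl[[i]] <- read_arr(int_off[i], int_len[i])
      if (any(intl[[i]] < 0)) stop("negative intensities in ibd at pixel ", i)
    }
    mz_range <- c(up("mz_range_lo"), up("mz_range_hi"))
    if (anyNA(mz_range)) mz_range <- range(unlist(mzl), c(0, Inf))
    msi_dataset(coords, mzl, intl, mode = "processed", pixel_size = px,
                polarity = polarity, mz_range = mz_range)
  }
}
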