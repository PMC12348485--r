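# imzML 1.1 I/O. The XML part is an mzML document with imaging (IMS) cvParams;
# the binary part (.ibd) starts with a 16-byte UUID followed by externally
# referenced arrays. m/z is stored as 64-bit float, intensities as 32-bit
# float (common imzML practice).

.uuid_bytes <- function(seed = NULL) {
  if (is.null(seed)) {
    b <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  } else {
    b <- with_local_seed(seed, as.raw(sample.int(256L, 16L, replace = TRUE) - 1L))
  }
  # RFC 4122 version/variant bits so external tools accept it
  b[7] <- as.raw(bitwAnd(as.integer(b[7]), 0x0FL) + 0x40L)
  b[9] <- as.raw(bitwAnd(as.integer(b[9]), 0x3FL) + 0x80L)
  b
}

.uuid_format <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  sub("^(.{8})(.{4})(.{4})(.{4})(.{12})$", "\\1-\\2-\\3-\\4-\\5", h)
}

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an MSI dataset as imzML + ibd
#'
#' @param dataset An `msi_dataset`.
#' @param path Output path for the `.imzML` file; the `.ibd` companion is
#'   written next to it.
#' @param mode `"processed"` (per-pixel m/z axes) or `"continuous"` (one
#'   shared axis). Continuous mode requires all pixels to share an identical
#'   axis unless a resampling `axis` is supplied.
#' @param axis Optional common m/z axis used to resample (nearest-bin
#'   accumulation) when writing continuous mode from processed data.
#' @param uuid_seed Optional integer; makes the embedded UUID (and hence the
#'   files) deterministic.
#' @return Invisibly, `c(imzml = path, ibd = ibd_path)`.
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous"),
                        axis = NULL, uuid_seed = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode)
  np <- n_pixels(dataset)
  mz_list <- dataset$mz_list
  int_list <- dataset$int_list

  if (mode == "continuous") {
    same_axis <- all(vapply(mz_list, identical, logical(1), y = mz_list[[1]]))
    if (!same_axis) {
      if (is.null(axis))
        stop("continuous-mode write of processed-mode data requires a resampling axis")
      int_list <- lapply(seq_len(np), function(i) {
        v <- numeric(length(axis))
        if (length(mz_list[[i]])) {
          bin <- pmin(pmax(findInterval(mz_list[[i]], axis, all.inside = TRUE), 1L),
                      length(axis))
          s <- rowsum(int_list[[i]], bin)
          v[as.integer(rownames(s))] <- s[, 1]
        }
        v
      })
      mz_list <- rep(list(axis), np)
    }
  }

  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uuid <- .uuid_bytes(uuid_seed)

  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  mz_off <- numeric(np); mz_len <- integer(np)
  int_off <- numeric(np); int_len <- integer(np)
  if (mode == "continuous") {
    ax <- mz_list[[1]]
    writeBin(as.numeric(ax), con, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(ax)
    offset <- offset + 8 * length(ax)
    for (i in seq_len(np)) {
      writeBin(as.numeric(int_list[[i]]), con, size = 4, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(int_list[[i]])
      offset <- offset + 4 * int_len[i]
    }
  } else {
    for (i in seq_len(np)) {
      writeBin(as.numeric(mz_list[[i]]), con, size = 8, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(mz_list[[i]])
      offset <- offset + 8 * mz_len[i]
      writeBin(as.numeric(int_list[[i]]), con, size = 4, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(int_list[[i]])
      offset <- offset + 4 * int_len[i]
    }
  }
  close(con)
  md5 <- unname(tools::md5sum(ibd_path))

  pol_acc <- if (dataset$polarity == "positive")
    c("MS:1000130", "positive scan") else c("MS:1000129", "negative scan")
  mode_acc <- if (mode == "continuous")
    c("IMS:1000030", "continuous") else c("IMS:1000031", "processed")

  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- sprintf(...)
  add('<?xml version="1.0" encoding="ISO-8859-1"?>')
  add('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">')
  add(' <cvList count="3">')
  add('  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>')
  add('  <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>')
  add('  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>')
  add(' </cvList>')
  add(' <fileDescription>')
  add('  <fileContent>')
  add('   <cvParam cvRef="IMS" accession="%s" name="%s" value=""/>', mode_acc[1], mode_acc[2])
  add('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', .uuid_format(uuid))
  add('   <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>', toupper(md5))
  add('   <userParam name="mz_range_lo" value="%.10g"/>', dataset$mz_range[1])
  add('   <userParam name="mz_range_hi" value="%.10g"/>', dataset$mz_range[2])
  add('  </fileContent>')
  add(' </fileDescription>')
  add(' <referenceableParamGroupList count="2">')
  add('  <referenceableParamGroup id="mzArray">')
  add('   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
  add('   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
  add('   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
  add('   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  add('  </referenceableParamGroup>')
  add('  <referenceableParamGroup id="intensityArray">')
  add('   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
  add('   <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>')
  add('   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
  add('   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  add('  </referenceableParamGroup>')
  add(' </referenceableParamGroupList>')
  add(' <softwareList count="1">')
  add('  <software id="lotusmsi" version="%s"/>', as.character(utils::packageVersion("lotusmsi")))
  add(' </softwareList>')
  add(' <scanSettingsList count="1">')
  add('  <scanSettings id="scansettings1">')
  add('   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', max(dataset$coords$x))
  add('   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', max(dataset$coords$y))
  add('   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%.10g"/>', dataset$pixel_size_um)
  add('   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%.10g"/>', dataset$pixel_size_um)
  add('  </scanSettings>')
  add(' </scanSettingsList>')
  add(' <instrumentConfigurationList count="1">')
  add('  <instrumentConfiguration id="instrument1"/>')
  add(' </instrumentConfigurationList>')
  add(' <dataProcessingList count="1">')
  add('  <dataProcessing id="export">')
  add('   <processingMethod order="1" softwareRef="lotusmsi">')
  add('    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
  add('   </processingMethod>')
  add('  </dataProcessing>')
  add(' </dataProcessingList>')
  add(' <run id="run1" defaultInstrumentConfigurationRef="instrument1">')
  add('  <spectrumList count="%d" defaultDataProcessingRef="export">', np)
  for (i in seq_len(np)) {
    add('   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">', i, i - 1L, int_len[i])
    add('    <cvParam cvRef="MS" accession="%s" name="%s" value=""/>', pol_acc[1], pol_acc[2])
    add('    <scanList count="1">')
    add('     <scan>')
    add('      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', dataset$coords$x[i])
    add('      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', dataset$coords$y[i])
    add('     </scan>')
    add('    </scanList>')
    add('    <binaryDataArrayList count="2">')
    add('     <binaryDataArray encodedLength="0">')
    add('      <referenceableParamGroupRef ref="mzArray"/>')
    add('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', mz_len[i])
    add('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', 8 * mz_len[i])
    add('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', mz_off[i])
    add('      <binary/>')
    add('     </binaryDataArray>')
    add('     <binaryDataArray encodedLength="0">')
    add('      <referenceableParamGroupRef ref="intensityArray"/>')
    add('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', int_len[i])
    add('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', 4 * int_len[i])
    add('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', int_off[i])
    add('      <binary/>')
    add('     </binaryDataArray>')
    add('    </binaryDataArrayList>')
    add('   </spectrum>')
  }
  add('  </spectrumList>')
  add(' </run>')
  add('</mzML>')
  con2 <- file(path, "wb")  # "wb" so line endings are stable across platforms
  writeLines(L, con2, sep = "\n")
  close(con2)
  invisible(c(imzml = path, ibd = ibd_path))
}

#' Read an imzML + ibd pair
#'
#' Both continuous and processed binary modes are supported. The ibd UUID and
#' MD5 checksum are verified against the XML; mismatches warn by default.
#' Spectra with unsorted m/z are repaired by sorting (with a warning).
#'
#' @param path Path to the `.imzML` file (`.ibd` expected alongside).
#' @param check `"warn"` (default) or `"fail"` on UUID/checksum mismatch.
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path, check = c("warn", "fail")) {
  check <- match.arg(check)
  complain <- if (check == "fail") stop else warning
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(path)) stop("imzML file not found: ", path)
  if (!file.exists(ibd_path)) stop("companion ibd file not found: ", ibd_path)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  cv1 <- function(node, acc)
    xml2::xml_attr(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", acc)), "value")

  fc <- xml2::xml_find_first(doc, ".//fileContent")
  mode <- if (!is.na(cv1(fc, "IMS:1000030"))) "continuous"
          else if (!is.na(cv1(fc, "IMS:1000031"))) "processed"
          else { complain("imzML does not declare continuous/processed mode; assuming processed"); "processed" }
  uuid_xml <- gsub("[{}-]", "", cv1(fc, "IMS:1000080"))
  md5_xml <- cv1(fc, "IMS:1000090")

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  uuid_ibd <- paste(format(readBin(con, "raw", 16L)), collapse = "")
  if (!is.na(uuid_xml) && nzchar(uuid_xml) &&
      tolower(uuid_xml) != tolower(uuid_ibd))
    complain("imzML/ibd UUID mismatch")
  if (!is.na(md5_xml) && nzchar(md5_xml) &&
      tolower(md5_xml) != tolower(unname(tools::md5sum(ibd_path))))
    complain("ibd MD5 checksum mismatch")

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(spectra) == 0L) stop("empty dataset: imzML contains no spectra")

  # vectorized cvParam harvesting relies on document order; each spectrum has
  # exactly one x, one y, and (mz, intensity) arrays in a fixed order when the
  # fast path is applicable
  g <- function(acc) as.numeric(xml2::xml_attr(
    xml2::xml_find_all(doc, sprintf(
      ".//spectrumList/spectrum//cvParam[@accession='%s']", acc)), "value"))
  xs <- g("IMS:1000050"); ys <- g("IMS:1000051")
  offs <- g("IMS:1000102"); lens <- g("IMS:1000103")
  np <- length(spectra)
  fast <- length(xs) == np && length(ys) == np &&
    length(offs) == 2L * np && length(lens) == 2L * np
  if (!fast) {
    xs <- ys <- numeric(np)
    offs <- lens <- numeric(2L * np)
    for (i in seq_len(np)) {
      s <- spectra[[i]]
      xs[i] <- as.numeric(cv1(s, "IMS:1000050"))
      ys[i] <- as.numeric(cv1(s, "IMS:1000051"))
      arr <- xml2::xml_find_all(s, ".//binaryDataArray")
      if (length(arr) != 2L) stop("spectrum ", i, ": expected 2 binary data arrays")
      for (j in 1:2) {
        offs[2L * (i - 1L) + j] <- as.numeric(cv1(arr[[j]], "IMS:1000102"))
        lens[2L * (i - 1L) + j] <- as.numeric(cv1(arr[[j]], "IMS:1000103"))
      }
    }
  }
  mz_off <- offs[seq(1L, by = 2L, length.out = np)]
  mz_len <- lens[seq(1L, by = 2L, length.out = np)]
  int_off <- offs[seq(2L, by = 2L, length.out = np)]
  int_len <- lens[seq(2L, by = 2L, length.out = np)]

  pol_pos <- length(xml2::xml_find_all(
    doc, ".//cvParam[@accession='MS:1000130']")) > 0
  polarity <- if (pol_pos) "positive" else "negative"

  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  px <- suppressWarnings(as.numeric(cv1(ss, "IMS:1000046")))
  if (is.na(px)) px <- 50
  up <- function(name) as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, sprintf(".//userParam[@name='%s']", name)), "value"))
  mz_lo <- up("mz_range_lo"); mz_hi <- up("mz_range_hi")

  read_arr <- function(off, len, size) {
    seek(con, where = off, origin = "start")
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  mz_list <- vector("list", np)
  int_list <- vector("list", np)
  if (mode == "continuous") {
    axis_cache <- new.env(parent = emptyenv())
    for (i in seq_len(np)) {
      key <- sprintf("o%.0f", mz_off[i])
      if (is.null(axis_cache[[key]]))
        axis_cache[[key]] <- read_arr(mz_off[i], mz_len[i], 8)
      mz_list[[i]] <- axis_cache[[key]]
      int_list[[i]] <- read_arr(int_off[i], int_len[i], 4)
    }
  } else {
    for (i in seq_len(np)) {
      mz_list[[i]] <- read_arr(mz_off[i], mz_len[i], 8)
      int_list[[i]] <- read_arr(int_off[i], int_len[i], 4)
    }
  }
  unsorted <- FALSE
  for (i in seq_len(np)) {
    if (is.unsorted(mz_list[[i]], strictly = TRUE)) {
      unsorted <- TRUE
      ord <- order(mz_list[[i]])
      mz_list[[i]] <- mz_list[[i]][ord]
      int_list[[i]] <- int_list[[i]][ord]
      if (anyDuplicated(mz_list[[i]])) {
        keep <- !duplicated(mz_list[[i]])
        int_list[[i]] <- as.numeric(rowsum(int_list[[i]], cumsum(keep)))
        mz_list[[i]] <- mz_list[[i]][keep]
      }
    }
  }
  if (unsorted) warning("unsorted m/z arrays were repaired by sorting")
  if (is.na(mz_lo)) mz_lo <- floor(min(unlist(lapply(mz_list, function(v) v[1]))))
  if (is.na(mz_hi)) mz_hi <- ceiling(max(unlist(lapply(mz_list, function(v) v[length(v)]))))

  msi_dataset(data.frame(x = xs, y = ys), mz_list, int_list,
              polarity = polarity, pixel_size_um = px,
              mz_range = c(mz_lo, mz_hi),
              shared_axis = (mode == "continuous"))
}
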