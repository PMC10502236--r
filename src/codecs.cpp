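// Per-tile image codecs: baseline JPEG (libjpeg) and JPEG 2000 codestreams
// (openjpeg). Tiles cross the R boundary as raw vectors of interleaved
// 8-bit RGB, row-major; streams are self-contained byte sequences.

#include <Rcpp.h>

#include <csetjmp>
#include <cstring>
#include <vector>

extern "C" {
#include <jpeglib.h>
#include <jerror.h>
#include <openjpeg.h>
}

using namespace Rcpp;

// ---------------------------------------------------------------------------
// libjpeg error handling: libjpeg's default error handler calls exit();
// replace it with longjmp back into the calling frame.
// ---------------------------------------------------------------------------

struct jerr_mgr {
  struct jpeg_error_mgr pub;
  jmp_buf setjmp_buffer;
  char msg[JMSG_LENGTH_MAX];
};

static void jerr_exit(j_common_ptr cinfo) {
  jerr_mgr* err = reinterpret_cast<jerr_mgr*>(cinfo->err);
  (*cinfo->err->format_message)(cinfo, err->msg);
  longjmp(err->setjmp_buffer, 1);
}

// [[Rcpp::export(name = ".cx_jpeg_encode")]]
RawVector cx_jpeg_encode(RawVector pixels, int width, int height, int quality) {
  if ((R_xlen_t)width * height * 3 != pixels.size())
    stop("pixel buffer size does not match %d x %d x 3", width, height);
  struct jpeg_compress_struct cinfo;
  jerr_mgr jerr;
  cinfo.err = jpeg_std_error(&jerr.pub);
  jerr.pub.error_exit = jerr_exit;

  unsigned char* outbuf = NULL;
  unsigned long outsize = 0;

  if (setjmp(jerr.setjmp_buffer)) {
    jpeg_destroy_compress(&cinfo);
    if (outbuf) free(outbuf);
    stop("JPEG encode failed: %s", jerr.msg);
  }

  jpeg_create_compress(&cinfo);
  jpeg_mem_dest(&cinfo, &outbuf, &outsize);

  cinfo.image_width = width;
  cinfo.image_height = height;
  cinfo.input_components = 3;
  cinfo.in_color_space = JCS_RGB;
  jpeg_set_defaults(&cinfo);
  jpeg_set_quality(&cinfo, quality, TRUE);
  jpeg_start_compress(&cinfo, TRUE);

  std::vector<unsigned char> row(width * 3);
  const unsigned char* src = RAW(pixels);
  while (cinfo.next_scanline < cinfo.image_height) {
    std::memcpy(row.data(), src + (size_t)cinfo.next_scanline * width * 3,
                (size_t)width * 3);
    JSAMPROW rp = row.data();
    jpeg_write_scanlines(&cinfo, &rp, 1);
  }
  jpeg_finish_compress(&cinfo);
  jpeg_destroy_compress(&cinfo);

  RawVector out(outsize);
  std::memcpy(RAW(out), outbuf, outsize);
  free(outbuf);
  return out;
}

// [[Rcpp::export(name = ".cx_jpeg_decode")]]
List cx_jpeg_decode(RawVector stream) {
  struct jpeg_decompress_struct cinfo;
  jerr_mgr jerr;
  cinfo.err = jpeg_std_error(&jerr.pub);
  jerr.pub.error_exit = jerr_exit;

  if (setjmp(jerr.setjmp_buffer)) {
    jpeg_destroy_decompress(&cinfo);
    stop("JPEG decode failed: %s", jerr.msg);
  }

  jpeg_create_decompress(&cinfo);
  jpeg_mem_src(&cinfo, RAW(stream), (unsigned long)stream.size());
  jpeg_read_header(&cinfo, TRUE);
  cinfo.out_color_space = JCS_RGB;  // grayscale/YCbCr sources normalized to RGB
  jpeg_start_decompress(&cinfo);

  int width = cinfo.output_width;
  int height = cinfo.output_height;
  RawVector out((R_xlen_t)width * height * 3);
  unsigned char* dst = RAW(out);
  while (cinfo.output_scanline < cinfo.output_height) {
    JSAMPROW rp = dst + (size_t)cinfo.output_scanline * width * 3;
    jpeg_read_scanlines(&cinfo, &rp, 1);
  }
  jpeg_finish_decompress(&cinfo);
  jpeg_destroy_decompress(&cinfo);

  return List::create(_["width"] = width, _["height"] = height,
                      _["channels"] = 3, _["data"] = out);
}

// ---------------------------------------------------------------------------
// openjpeg memory streams: openjpeg writes with backward seeks (to patch
// lengths), so the output buffer must be random-access.
// ---------------------------------------------------------------------------

struct opj_membuf {
  std::vector<unsigned char> buf;  // write target
  const unsigned char* rdata;      // read source
  OPJ_SIZE_T rsize;
  OPJ_SIZE_T pos;
};

static OPJ_SIZE_T mem_read(void* dest, OPJ_SIZE_T n, void* user) {
  opj_membuf* m = static_cast<opj_membuf*>(user);
  if (m->pos >= m->rsize) return (OPJ_SIZE_T)-1;
  OPJ_SIZE_T take = std::min(n, m->rsize - m->pos);
  std::memcpy(dest, m->rdata + m->pos, take);
  m->pos += take;
  return take;
}

static OPJ_SIZE_T mem_write(void* src, OPJ_SIZE_T n, void* user) {
  opj_membuf* m = static_cast<opj_membuf*>(user);
  if (m->pos + n > m->buf.size()) m->buf.resize(m->pos + n);
  std::memcpy(m->buf.data() + m->pos, src, n);
  m->pos += n;
  return n;
}

static OPJ_OFF_T mem_skip(OPJ_OFF_T n, void* user) {
  opj_membuf* m = static_cast<opj_membuf*>(user);
  m->pos += n;
  return n;
}

static OPJ_BOOL mem_seek(OPJ_OFF_T n, void* user) {
  opj_membuf* m = static_cast<opj_membuf*>(user);
  if (n < 0) return OPJ_FALSE;
  m->pos = (OPJ_SIZE_T)n;
  return OPJ_TRUE;
}

static void opj_quiet(const char*, void*) {}

// [[Rcpp::export(name = ".cx_j2k_encode")]]
RawVector cx_j2k_encode(RawVector pixels, int width, int height) {
  if ((R_xlen_t)width * height * 3 != pixels.size())
    stop("pixel buffer size does not match %d x %d x 3", width, height);

  opj_cparameters_t parameters;
  opj_set_default_encoder_parameters(&parameters);
  parameters.tcp_numlayers = 1;
  parameters.tcp_rates[0] = 0;  // lossless
  parameters.cp_disto_alloc = 1;
  parameters.irreversible = 0;  // reversible 5/3 wavelet

  // each resolution level halves the image; tiny tiles need fewer levels
  int maxres = 1;
  int mindim = std::min(width, height);
  while (maxres < 6 && (mindim >> maxres) > 0) ++maxres;
  parameters.numresolution = maxres;

  opj_image_cmptparm_t cmpt[3];
  std::memset(cmpt, 0, sizeof(cmpt));
  for (int c = 0; c < 3; ++c) {
    cmpt[c].dx = 1;
    cmpt[c].dy = 1;
    cmpt[c].w = width;
    cmpt[c].h = height;
    cmpt[c].prec = 8;
    cmpt[c].sgnd = 0;
  }
  opj_image_t* image = opj_image_create(3, cmpt, OPJ_CLRSPC_SRGB);
  if (!image) stop("JPEG 2000 encode: image allocation failed");
  image->x0 = 0;
  image->y0 = 0;
  image->x1 = width;
  image->y1 = height;

  const unsigned char* src = RAW(pixels);
  size_t npx = (size_t)width * height;
  for (size_t i = 0; i < npx; ++i) {
    image->comps[0].data[i] = src[3 * i];
    image->comps[1].data[i] = src[3 * i + 1];
    image->comps[2].data[i] = src[3 * i + 2];
  }

  opj_codec_t* codec = opj_create_compress(OPJ_CODEC_J2K);
  opj_set_info_handler(codec, opj_quiet, NULL);
  opj_set_warning_handler(codec, opj_quiet, NULL);
  opj_set_error_handler(codec, opj_quiet, NULL);
  if (!opj_setup_encoder(codec, &parameters, image)) {
    opj_destroy_codec(codec);
    opj_image_destroy(image);
    stop("JPEG 2000 encoder setup failed");
  }

  opj_membuf mb;
  mb.pos = 0;
  mb.rdata = NULL;
  mb.rsize = 0;
  opj_stream_t* stream = opj_stream_default_create(OPJ_FALSE);
  opj_stream_set_user_data(stream, &mb, NULL);
  opj_stream_set_write_function(stream, mem_write);
  opj_stream_set_skip_function(stream, mem_skip);
  opj_stream_set_seek_function(stream, mem_seek);

  OPJ_BOOL ok = opj_start_compress(codec, image, stream) &&
                opj_encode(codec, stream) && opj_end_compress(codec, stream);
  opj_stream_destroy(stream);
  opj_destroy_codec(codec);
  opj_image_destroy(image);
  if (!ok) stop("JPEG 2000 encode failed");

  RawVector out(mb.buf.size());
  std::memcpy(RAW(out), mb.buf.data(), mb.buf.size());
  return out;
}

// [[Rcpp::export(name = ".cx_j2k_decode")]]
List cx_j2k_decode(RawVector stream_bytes) {
  opj_membuf mb;
  mb.rdata = RAW(stream_bytes);
  mb.rsize = (OPJ_SIZE_T)stream_bytes.size();
  mb.pos = 0;

  // raw codestream (SOC marker) vs JP2 box container
  OPJ_CODEC_FORMAT fmt = OPJ_CODEC_J2K;
  if (stream_bytes.size() >= 4 && stream_bytes[0] == 0x00 &&
      stream_bytes[1] == 0x00 && stream_bytes[2] == 0x00 &&
      stream_bytes[3] == 0x0C)
    fmt = OPJ_CODEC_JP2;

  opj_codec_t* codec = opj_create_decompress(fmt);
  opj_set_info_handler(codec, opj_quiet, NULL);
  opj_set_warning_handler(codec, opj_quiet, NULL);
  opj_set_error_handler(codec, opj_quiet, NULL);
  opj_dparameters_t parameters;
  opj_set_default_decoder_parameters(&parameters);
  if (!opj_setup_decoder(codec, &parameters)) {
    opj_destroy_codec(codec);
    stop("JPEG 2000 decoder setup failed");
  }

  opj_stream_t* stream = opj_stream_default_create(OPJ_TRUE);
  opj_stream_set_user_data(stream, &mb, NULL);
  opj_stream_set_user_data_length(stream, mb.rsize);
  opj_stream_set_read_function(stream, mem_read);
  opj_stream_set_skip_function(stream, mem_skip);
  opj_stream_set_seek_function(stream, mem_seek);

  opj_image_t* image = NULL;
  OPJ_BOOL ok = opj_read_header(stream, codec, &image) &&
                opj_decode(codec, stream, image) &&
                opj_end_decompress(codec, stream);
  opj_stream_destroy(stream);
  opj_destroy_codec(codec);
  if (!ok || !image) {
    if (image) opj_image_destroy(image);
    stop("JPEG 2000 decode failed");
  }

  int width = image->comps[0].w;
  int height = image->comps[0].h;
  int ncomp = image->numcomps;
  RawVector out((R_xlen_t)width * height * 3);
  unsigned char* dst = RAW(out);
  size_t npx = (size_t)width * height;
  for (size_t i = 0; i < npx; ++i) {
    for (int c = 0; c < 3; ++c) {
      int v = image->comps[ncomp == 3 ? c : 0].data[i];
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      dst[3 * i + c] = (unsigned char)v;
    }
  }
  opj_image_destroy(image);
  return List::create(_["width"] = width, _["height"] = height,
                      _["channels"] = 3, _["data"] = out);
}
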