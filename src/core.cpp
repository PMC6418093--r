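#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic, platform-independent RNG for frame rendering.
// splitmix64 for seeding, xoshiro-style stream per frame, Box-Muller normals.
// R's own RNG is reserved for trajectory simulation; rendering must be
// randomly accessible per frame (lazy streams), hence a counter-based seed.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct FrameRng {
  uint64_t s[2];
  FrameRng(uint64_t seed, uint64_t frame) {
    uint64_t x = seed ^ (frame * 0x9E3779B97F4A7C15ULL + 0x243F6A8885A308D3ULL);
    s[0] = splitmix64(x);
    s[1] = splitmix64(x);
  }
  inline uint64_t next() {
    uint64_t s0 = s[0], s1 = s[1];
    uint64_t r = s0 + s1;
    s1 ^= s0;
    s[0] = ((s0 << 55) | (s0 >> 9)) ^ s1 ^ (s1 << 14);
    s[1] = (s1 << 36) | (s1 >> 28);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// KNN background model.
// Per-pixel stored samples: the previous frame (age 1) plus a ring of
// `nsamples` snapshots taken every `interval` frames (ages up to
// nsamples*interval ~= history_frames). A pixel is foreground when fewer than
// k stored samples lie within the squared-intensity distance threshold.
// Fully deterministic: no random replacement.
// ---------------------------------------------------------------------------

struct BgModel {
  int w, h, nsamples, interval;
  long frame_count;
  bool has_prev;
  std::vector<uint8_t> prev;
  std::vector<uint8_t> ring;    // nsamples * npix
  std::vector<uint8_t> filled;  // per ring slot
  BgModel(int w_, int h_, int nsamples_, int interval_)
      : w(w_), h(h_), nsamples(nsamples_), interval(interval_),
        frame_count(0), has_prev(false),
        prev((size_t)w_ * h_, 0),
        ring((size_t)w_ * h_ * nsamples_, 0),
        filled(nsamples_, 0) {}
};

// [[Rcpp::export(name = ".cppBgModelNew")]]
SEXP cppBgModelNew(int width, int height, int nsamples, int interval) {
  XPtr<BgModel> p(new BgModel(width, height, nsamples, interval), true);
  return p;
}

// [[Rcpp::export(name = ".cppBgModelFrameCount")]]
double cppBgModelFrameCount(SEXP model) {
  XPtr<BgModel> m(model);
  return (double)m->frame_count;
}

// frame: H x W integer matrix (0..255). Returns H x W logical foreground mask.
// [[Rcpp::export(name = ".cppBgApply")]]
LogicalMatrix cppBgApply(SEXP model, IntegerMatrix frame, double threshold,
                         int k, bool update = true) {
  XPtr<BgModel> m(model);
  const int h = m->h, w = m->w;
  if (frame.nrow() != h || frame.ncol() != w)
    stop("frame geometry does not match background model");
  const size_t npix = (size_t)h * w;
  LogicalMatrix mask(h, w);
  const int ns = m->nsamples;
  // classification
  if (m->has_prev) {
    const uint8_t *prev = m->prev.data();
    const uint8_t *ring = m->ring.data();
    const uint8_t *filled = m->filled.data();
    const int *fr = INTEGER(frame);
    int *out = LOGICAL(mask);
    for (size_t i = 0; i < npix; ++i) {
      const double v = (double)fr[i];
      int cnt = 0;
      double d = v - (double)prev[i];
      if (d * d <= threshold) cnt++;
      if (cnt < k) {
        for (int s = 0; s < ns; ++s) {
          if (!filled[s]) continue;
          d = v - (double)ring[(size_t)s * npix + i];
          if (d * d <= threshold) {
            if (++cnt >= k) break;
          }
        }
      }
      out[i] = (cnt < k);
    }
  }
  // else: first frame, all background (warm-up covers this)
  if (update) {
    const int *fr = INTEGER(frame);
    if (m->interval > 0 && (m->frame_count % m->interval) == 0) {
      int slot = (int)((m->frame_count / m->interval) % ns);
      uint8_t *dst = m->ring.data() + (size_t)slot * npix;
      for (size_t i = 0; i < npix; ++i) dst[i] = (uint8_t)fr[i];
      m->filled[slot] = 1;
    }
    uint8_t *pv = m->prev.data();
    for (size_t i = 0; i < npix; ++i) pv[i] = (uint8_t)fr[i];
    m->has_prev = true;
    m->frame_count++;
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Gaussian blur of a binary mask (separable, replicated border), then
// re-threshold at 0.5. sigma follows the usual kernel-size heuristic.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cppBlurThreshold")]]
LogicalMatrix cppBlurThreshold(LogicalMatrix mask, int ksize) {
  const int h = mask.nrow(), w = mask.ncol();
  if (ksize <= 1) return mask;
  if (ksize % 2 == 0) stop("blur kernel size must be odd");
  const int r = ksize / 2;
  double sigma = 0.3 * ((ksize - 1) * 0.5 - 1.0) + 0.8;
  std::vector<double> kern(ksize);
  double s = 0;
  for (int i = 0; i < ksize; ++i) {
    double x = i - r;
    kern[i] = std::exp(-0.5 * x * x / (sigma * sigma));
    s += kern[i];
  }
  for (int i = 0; i < ksize; ++i) kern[i] /= s;

  std::vector<double> tmp((size_t)h * w), tmp2((size_t)h * w);
  const int *in = LOGICAL(mask);
  // horizontal pass (R matrices are column-major: index i + h*j)
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0;
        if (jj >= w) jj = w - 1;
        acc += kern[t + r] * (in[i + (size_t)h * jj] ? 1.0 : 0.0);
      }
      tmp[i + (size_t)h * j] = acc;
    }
  }
  // vertical pass
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0;
        if (ii >= h) ii = h - 1;
        acc += kern[t + r] * tmp[ii + (size_t)h * j];
      }
      tmp2[i + (size_t)h * j] = acc;
    }
  }
  LogicalMatrix out(h, w);
  int *o = LOGICAL(out);
  for (size_t i = 0; i < (size_t)h * w; ++i) o[i] = (tmp2[i] >= 0.5);
  return out;
}

// ---------------------------------------------------------------------------
// Morphology with a disc (elliptical) structuring element of size k x k.
// k = 3 gives the 4-connected cross, matching the usual elliptical SE.
// Out-of-frame treated as background.
// ---------------------------------------------------------------------------

static std::vector<std::pair<int, int>> disc_offsets(int ksize) {
  int r = ksize / 2;
  std::vector<std::pair<int, int>> off;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if (dx * dx + dy * dy <= r * r) off.push_back({dy, dx});
  return off;
}

static LogicalMatrix morph_once(const LogicalMatrix &mask, int ksize, bool dilate) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix out(h, w);
  const int *in = LOGICAL(mask);
  int *o = LOGICAL(out);
  auto off = disc_offsets(ksize);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      bool v = !dilate;  // erode: AND-init true; dilate: OR-init false
      for (auto &d : off) {
        int ii = i + d.first, jj = j + d.second;
        bool px = (ii >= 0 && ii < h && jj >= 0 && jj < w)
                      ? (bool)in[ii + (size_t)h * jj]
                      : false;
        if (dilate) {
          if (px) { v = true; break; }
        } else {
          if (!px) { v = false; break; }
        }
      }
      o[i + (size_t)h * j] = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cppMorph")]]
LogicalMatrix cppMorph(LogicalMatrix mask, int ksize, std::string op) {
  if (ksize <= 1) return mask;
  if (op == "erode") return morph_once(mask, ksize, false);
  if (op == "dilate") return morph_once(mask, ksize, true);
  if (op == "close") return morph_once(morph_once(mask, ksize, true), ksize, false);
  if (op == "open") return morph_once(morph_once(mask, ksize, false), ksize, true);
  stop("unknown morphological operation '%s'", op.c_str());
}

// ---------------------------------------------------------------------------
// Connected components, 8-connectivity, iterative flood fill.
// Centroids are returned in continuous frame coordinates (pixel (row i, col j)
// has centre x = j - 0.5, y = i - 0.5 with 1-based R indices).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cppComponents")]]
List cppComponents(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  const int *in = LOGICAL(mask);
  IntegerMatrix labels(h, w);
  int *lab = INTEGER(labels);
  std::vector<double> cx, cy;
  std::vector<int> area;
  std::vector<int> stack;
  int ncomp = 0;
  for (int j0 = 0; j0 < w; ++j0) {
    for (int i0 = 0; i0 < h; ++i0) {
      size_t idx0 = i0 + (size_t)h * j0;
      if (!in[idx0] || lab[idx0]) continue;
      ncomp++;
      long a = 0;
      double sx = 0, sy = 0;
      lab[idx0] = ncomp;
      stack.push_back((int)idx0);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int i = idx % h, j = idx / h;
        a++;
        sx += j + 0.5;  // 0-based col centre -> continuous x
        sy += i + 0.5;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
            size_t nidx = ii + (size_t)h * jj;
            if (in[nidx] && !lab[nidx]) {
              lab[nidx] = ncomp;
              stack.push_back((int)nidx);
            }
          }
        }
      }
      area.push_back((int)a);
      cx.push_back(sx / a);
      cy.push_back(sy / a);
    }
  }
  return List::create(_["n"] = ncomp, _["labels"] = labels,
                      _["area"] = wrap(area), _["x"] = wrap(cx),
                      _["y"] = wrap(cy));
}

// ---------------------------------------------------------------------------
// Renderer: bright uniform background, anti-aliased dark discs, additive
// Gaussian noise, clipped to 8 bits. Coordinates: continuous, origin at the
// top-left frame corner; pixel (i, j) (0-based) has centre (j + 0.5, i + 0.5).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cppRenderFrame")]]
IntegerMatrix cppRenderFrame(int width, int height, NumericVector x,
                             NumericVector y, double flyRadius,
                             double backgroundLevel, double flyLevel,
                             double noiseSd, double seed, int frameIndex) {
  const int h = height, w = width;
  IntegerMatrix out(h, w);
  int *o = INTEGER(out);
  std::vector<double> img((size_t)h * w, backgroundLevel);
  const int n = x.size();
  for (int f = 0; f < n; ++f) {
    double fx = x[f], fy = y[f];
    int j0 = std::max(0, (int)std::floor(fx - flyRadius - 1.5));
    int j1 = std::min(w - 1, (int)std::ceil(fx + flyRadius + 1.5));
    int i0 = std::max(0, (int)std::floor(fy - flyRadius - 1.5));
    int i1 = std::min(h - 1, (int)std::ceil(fy + flyRadius + 1.5));
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double dx = (j + 0.5) - fx, dy = (i + 0.5) - fy;
        double d = std::sqrt(dx * dx + dy * dy);
        double cov = flyRadius + 0.5 - d;  // linear anti-aliasing ramp
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        double v = backgroundLevel + (flyLevel - backgroundLevel) * cov;
        size_t idx = i + (size_t)h * j;
        if (v < img[idx]) img[idx] = v;  // overlapping flies: darkest wins
      }
    }
  }
  if (noiseSd > 0) {
    FrameRng rng((uint64_t)seed, (uint64_t)frameIndex);
    for (size_t i = 0; i < (size_t)h * w; ++i) img[i] += noiseSd * rng.norm();
  }
  for (size_t i = 0; i < (size_t)h * w; ++i) {
    double v = std::nearbyint(img[i]);
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    o[i] = (int)v;
  }
  return out;
}
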