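#include <Rcpp.h>
#include <cstdio>
#include <string>

using namespace Rcpp;

// Canonical JSON emitter: 2-space indent, LF only, no trailing whitespace,
// element order = list order.  Conventions for the R tree:
//   * named list            -> object (NULL members are skipped)
//   * list of class json_array -> array
//   * character(1)          -> string (UTF-8)
//   * character(1) of class json_number -> emitted verbatim (decimal literals)
//   * logical(1)/integer(1) -> true/false / integer literal
//   * double(1)             -> %.15g (used only as a fallback; the compiler
//                              carries decimals as json_number verbatim text)

static void emit_string(std::string &out, const char *s) {
  out += '"';
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    unsigned char c = *p;
    switch (c) {
    case '"':  out += "\\\""; break;
    case '\\': out += "\\\\"; break;
    case '\n': out += "\\n";  break;
    case '\r': out += "\\r";  break;
    case '\t': out += "\\t";  break;
    case '\b': out += "\\b";  break;
    case '\f': out += "\\f";  break;
    default:
      if (c < 0x20) {
        char buf[8];
        snprintf(buf, sizeof(buf), "\\u%04x", (unsigned int)c);
        out += buf;
      } else {
        out += (char)c;
      }
    }
  }
  out += '"';
}

static void indent_to(std::string &out, int depth) {
  out.append((size_t)depth * 2, ' ');
}

static bool is_json_array(SEXP x) {
  return Rf_inherits(x, "json_array");
}

static void emit(std::string &out, SEXP x, int depth);

static void emit_array(std::string &out, SEXP x, int depth) {
  R_xlen_t n = Rf_xlength(x);
  if (n == 0) { out += "[]"; return; }
  out += "[\n";
  for (R_xlen_t i = 0; i < n; ++i) {
    indent_to(out, depth + 1);
    emit(out, VECTOR_ELT(x, i), depth + 1);
    if (i < n - 1) out += ',';
    out += '\n';
  }
  indent_to(out, depth);
  out += ']';
}

static void emit_object(std::string &out, SEXP x, int depth) {
  R_xlen_t n = Rf_xlength(x);
  SEXP names = Rf_getAttrib(x, R_NamesSymbol);
  if (names == R_NilValue)
    stop("object node without names in JSON tree");
  // count non-NULL members first
  R_xlen_t kept = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (VECTOR_ELT(x, i) != R_NilValue) ++kept;
  if (kept == 0) { out += "{}"; return; }
  out += "{\n";
  R_xlen_t seen = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP v = VECTOR_ELT(x, i);
    if (v == R_NilValue) continue;
    ++seen;
    indent_to(out, depth + 1);
    emit_string(out, Rf_translateCharUTF8(STRING_ELT(names, i)));
    out += ": ";
    emit(out, v, depth + 1);
    if (seen < kept) out += ',';
    out += '\n';
  }
  indent_to(out, depth);
  out += '}';
}

static void emit(std::string &out, SEXP x, int depth) {
  switch (TYPEOF(x)) {
  case VECSXP:
    if (is_json_array(x)) emit_array(out, x, depth);
    else emit_object(out, x, depth);
    return;
  case STRSXP:
    if (Rf_xlength(x) != 1) stop("string node must have length 1");
    if (Rf_inherits(x, "json_number") || Rf_inherits(x, "json_verbatim"))
      out += Rf_translateCharUTF8(STRING_ELT(x, 0));
    else
      emit_string(out, Rf_translateCharUTF8(STRING_ELT(x, 0)));
    return;
  case LGLSXP: {
    if (Rf_xlength(x) != 1) stop("logical node must have length 1");
    int v = LOGICAL(x)[0];
    if (v == NA_LOGICAL) stop("NA logical in JSON tree");
    out += v ? "true" : "false";
    return;
  }
  case INTSXP: {
    if (Rf_xlength(x) != 1) stop("integer node must have length 1");
    int v = INTEGER(x)[0];
    if (v == NA_INTEGER) stop("NA integer in JSON tree");
    char buf[16];
    snprintf(buf, sizeof(buf), "%d", v);
    out += buf;
    return;
  }
  case REALSXP: {
    if (Rf_xlength(x) != 1) stop("double node must have length 1");
    double v = REAL(x)[0];
    if (ISNAN(v)) stop("NA/NaN double in JSON tree");
    if (v == (double)(long long)v && v > -1e15 && v < 1e15) {
      char buf[32];
      snprintf(buf, sizeof(buf), "%lld", (long long)v);
      out += buf;
    } else {
      char buf[40];
      snprintf(buf, sizeof(buf), "%.15g", v);
      out += buf;
    }
    return;
  }
  case NILSXP:
    out += "null";
    return;
  default:
    stop("unsupported node type in JSON tree: %s", Rf_type2char((SEXPTYPE)TYPEOF(x)));
  }
}

// [[Rcpp::export(name = ".json_emit")]]
CharacterVector json_emit(SEXP x) {
  std::string out;
  out.reserve(1 << 16);
  emit(out, x, 0);
  out += '\n';
  CharacterVector res(1);
  res[0] = Rf_mkCharLenCE(out.data(), (int)out.size(), CE_UTF8);
  return res;
}
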