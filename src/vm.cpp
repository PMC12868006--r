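// Multi-lane stack virtual machine core.
//
// Words are raw 64-bit quantities; almost all operations view them as IEEE
// double bit patterns (the value-cast pair LONGLONGTODOUBLE/DOUBLETOLONGLONG
// moves between the double view and a signed-integer view).  Each lane owns a
// fixed-capacity stack and a private heap arena; lanes communicate only
// through the named host environment buffers.  Scheduling is deterministic
// round-robin, one instruction per running lane per round, so reports are
// bit-reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <cstdio>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// instruction codes (order fixed; mirrored by R constant BC_INSTRUCTIONS)
enum InstrCode {
  I_OP = 0, I_VALUE, I_JUMP, I_JUMPIFZERO, I_SI_VALUE_OP, I_SI_OP_VALUE
};

// operation ids: the C++ table below is the single source of truth; R builds
// its opcode table from cpp_op_table().
enum OpId {
  OP_OPNULL = 0,
  // stack access / pointer arithmetic
  OP_SREAD, OP_SWRITE, OP_SADD_P, OP_SSUB_P, OP_DUP, OP_DROP,
  // basic arithmetic and logic
  OP_ADD, OP_SUB, OP_MUL, OP_DIV, OP_NEG, OP_AND, OP_OR, OP_NOT, OP_SWAP,
  // memory management & ternary
  OP_MALLOC, OP_FREE, OP_MEMCPY, OP_TERNARY,
  // comparison
  OP_EQ, OP_NEQ, OP_GT, OP_LT, OP_GTEQ, OP_LTEQ,
  // extra memory access
  OP_PTR_DEREF, OP_PTR_STORE,
  // floating point I/O
  OP_READ_F64, OP_WRITE_F64, OP_READ_F32, OP_WRITE_F32,
  // integer I/O
  OP_READ_I32, OP_WRITE_I32,
  // character I/O
  OP_READ_CHAR, OP_WRITE_CHAR,
  // mathematical functions
  OP_ACOS, OP_ASIN, OP_ATAN, OP_SIN, OP_COS, OP_TAN,
  OP_SQRT, OP_LOG, OP_EXP, OP_ERF, OP_ABS, OP_FLOOR, OP_POW, OP_FMOD,
  // system calls
  OP_PRINTC, OP_PRINTF,
  // type casting (value conversions; see package docs)
  OP_DOUBLETOLONGLONG, OP_LONGLONGTODOUBLE,
  // environment operations
  OP_LDPC, OP_LDTID, OP_LDSTK_PTR,
  // synchronization
  OP_SYNCWARP, OP_SYNCBLOCK, OP_SYNCGRID,
  OP__COUNT
};

struct OpInfo { const char* name; const char* category; int in; int out; };

static const OpInfo OP_TABLE[OP__COUNT] = {
  {"OPNULL",           "null",        0, 0},
  {"SREAD",            "stack",       1, 1},
  {"SWRITE",           "stack",       2, 0},
  {"SADD_P",           "stack",       2, 1},
  {"SSUB_P",           "stack",       2, 1},
  {"DUP",              "stack",       1, 2},
  {"DROP",             "stack",       1, 0},
  {"ADD",              "arithmetic",  2, 1},
  {"SUB",              "arithmetic",  2, 1},
  {"MUL",              "arithmetic",  2, 1},
  {"DIV",              "arithmetic",  2, 1},
  {"NEG",              "arithmetic",  1, 1},
  {"AND",              "arithmetic",  2, 1},
  {"OR",               "arithmetic",  2, 1},
  {"NOT",              "arithmetic",  1, 1},
  {"SWAP",             "arithmetic",  2, 2},
  {"MALLOC",           "memory",      1, 1},
  {"FREE",             "memory",      1, 0},
  {"MEMCPY",           "memory",      3, 0},
  {"TERNARY",          "memory",      3, 1},
  {"EQ",               "comparison",  2, 1},
  {"NEQ",              "comparison",  2, 1},
  {"GT",               "comparison",  2, 1},
  {"LT",               "comparison",  2, 1},
  {"GTEQ",             "comparison",  2, 1},
  {"LTEQ",             "comparison",  2, 1},
  {"PTR_DEREF",        "extra_memory", 1, 1},
  {"PTR_STORE",        "extra_memory", 2, 0},
  {"READ_F64",         "float_io",    2, 1},
  {"WRITE_F64",        "float_io",    3, 0},
  {"READ_F32",         "float_io",    2, 1},
  {"WRITE_F32",        "float_io",    3, 0},
  {"READ_I32",         "integer_io",  2, 1},
  {"WRITE_I32",        "integer_io",  3, 0},
  {"READ_CHAR",        "char_io",     2, 1},
  {"WRITE_CHAR",       "char_io",     3, 0},
  {"ACOS",             "math",        1, 1},
  {"ASIN",             "math",        1, 1},
  {"ATAN",             "math",        1, 1},
  {"SIN",              "math",        1, 1},
  {"COS",              "math",        1, 1},
  {"TAN",              "math",        1, 1},
  {"SQRT",             "math",        1, 1},
  {"LOG",              "math",        1, 1},
  {"EXP",              "math",        1, 1},
  {"ERF",              "math",        1, 1},
  {"ABS",              "math",        1, 1},
  {"FLOOR",            "math",        1, 1},
  {"POW",              "math",        2, 1},
  {"FMOD",             "math",        2, 1},
  {"PRINTC",           "syscall",     1, 0},
  {"PRINTF",           "syscall",     1, 0},
  {"DOUBLETOLONGLONG", "cast",        1, 1},
  {"LONGLONGTODOUBLE", "cast",        1, 1},
  {"LDPC",             "environment", 0, 1},
  {"LDTID",            "environment", 0, 1},
  {"LDSTK_PTR",        "environment", 0, 1},
  {"SYNCWARP",         "sync",        0, 0},
  {"SYNCBLOCK",        "sync",        0, 0},
  {"SYNCGRID",         "sync",        0, 0}
};

static inline double w2d(uint64_t w) { double d; std::memcpy(&d, &w, 8); return d; }
static inline uint64_t d2w(double d) { uint64_t w; std::memcpy(&w, &d, 8); return w; }
static inline int64_t w2i(uint64_t w) { int64_t i; std::memcpy(&i, &w, 8); return i; }
static inline uint64_t i2w(int64_t i) { uint64_t w; std::memcpy(&w, &i, 8); return w; }

// lane status
enum LaneStatus { ST_RUNNING = 0, ST_HALTED, ST_BLOCKED, ST_FAULT, ST_STEPLIMIT };
static const char* STATUS_NAMES[] =
  {"running", "halted", "blocked", "faulted", "step-limit"};

struct Alloc { int64_t off; int64_t len; bool live; };

struct Lane {
  int64_t pc = 0;
  int64_t sp = 0;
  int tid = 0;
  int status = ST_RUNNING;
  std::string fault_reason;
  std::vector<uint64_t> stack;
  std::vector<uint64_t> heap;
  int64_t hp = 0;                 // bump pointer
  std::vector<Alloc> allocs;
  int64_t steps = 0;
  int barrier = -1;               // 0 warp, 1 block, 2 grid (while blocked)
};

enum BufType { T_F64 = 0, T_F32, T_I32, T_CHAR };

struct EnvBuf {
  std::string name;
  int type;
  std::vector<double> f64;
  std::vector<float> f32;
  std::vector<int32_t> i32;
  std::vector<uint8_t> ch;
  size_t len() const {
    switch (type) {
      case T_F64: return f64.size();
      case T_F32: return f32.size();
      case T_I32: return i32.size();
      default:    return ch.size();
    }
  }
};

struct Vm {
  std::vector<int> instr;
  std::vector<int> ops;      // -1 means null slot
  std::vector<double> vals;
  std::vector<Lane> lanes;
  std::vector<EnvBuf> env;
  int64_t stack_cap = 0;
  int64_t heap_words = 0;
  int64_t max_steps = 0;
  int warp_size = 32;
  std::string console;
  bool finished = false;
  int64_t n() const { return (int64_t)instr.size(); }
};

static inline void lane_fault(Lane& L, const std::string& msg) {
  L.status = ST_FAULT;
  L.fault_reason = msg;
}

static inline bool push_w(Vm& V, Lane& L, uint64_t w) {
  if (L.sp >= V.stack_cap) { lane_fault(L, "stack overflow"); return false; }
  L.stack[(size_t)L.sp++] = w;
  return true;
}
static inline bool pop_w(Lane& L, uint64_t& w) {
  if (L.sp <= 0) { lane_fault(L, "stack underflow"); return false; }
  w = L.stack[(size_t)--L.sp];
  return true;
}
static inline bool push_d(Vm& V, Lane& L, double d) { return push_w(V, L, d2w(d)); }
static inline bool pop_d(Lane& L, double& d) {
  uint64_t w;
  if (!pop_w(L, w)) return false;
  d = w2d(w);
  return true;
}

// integral index in [lo, hi]; false on non-integral / NaN / out of range
static inline bool as_index(double d, int64_t lo, int64_t hi, int64_t& out) {
  if (std::isnan(d) || std::floor(d) != d) return false;
  if (d < (double)lo || d > (double)hi) return false;
  out = (int64_t)d;
  return true;
}

// heap range [addr, addr+count) must sit inside one live allocation
static bool heap_range_ok(Lane& L, int64_t addr, int64_t count) {
  for (size_t k = 0; k < L.allocs.size(); ++k) {
    const Alloc& a = L.allocs[k];
    if (a.live && addr >= a.off && addr + count <= a.off + a.len) return true;
  }
  return false;
}

static void append_printf(Vm& V, double d) {
  char buf[64];
  if (std::isfinite(d) && std::floor(d) == d && std::fabs(d) < 9.007199254740992e15) {
    std::snprintf(buf, sizeof(buf), "%lld", (long long)d);
  } else {
    std::snprintf(buf, sizeof(buf), "%g", d);
  }
  V.console += buf;
}

// Execute one operation on a lane.  pc_cur is the index of the instruction
// that carried the op (LDPC pushes it).
static void exec_op(Vm& V, Lane& L, int op, int64_t pc_cur) {
  double a, b, c;
  uint64_t w;
  switch (op) {
    case OP_OPNULL: break;

    case OP_SREAD: {
      if (!pop_d(L, a)) return;
      int64_t off;
      if (!as_index(a, 1, L.sp, off)) { lane_fault(L, "SREAD offset out of range"); return; }
      push_w(V, L, L.stack[(size_t)(L.sp - off)]);
      break;
    }
    case OP_SWRITE: {
      if (!pop_d(L, a)) return;           // offset
      if (!pop_w(L, w)) return;           // value
      int64_t off;
      if (!as_index(a, 1, L.sp, off)) { lane_fault(L, "SWRITE offset out of range"); return; }
      L.stack[(size_t)(L.sp - off)] = w;
      break;
    }
    case OP_SADD_P:
      if (!pop_d(L, b) || !pop_d(L, a)) return;
      push_d(V, L, a + b);
      break;
    case OP_SSUB_P:
      if (!pop_d(L, b) || !pop_d(L, a)) return;
      push_d(V, L, a - b);
      break;
    case OP_DUP:
      if (!pop_w(L, w)) return;
      if (!push_w(V, L, w)) return;
      push_w(V, L, w);
      break;
    case OP_DROP:
      pop_w(L, w);
      break;

    case OP_ADD: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, a + b); break;
    case OP_SUB: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, a - b); break;
    case OP_MUL: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, a * b); break;
    case OP_DIV: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, a / b); break;
    case OP_NEG: if (pop_d(L, a)) push_d(V, L, -a); break;
    case OP_AND:
      if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a != 0.0 && b != 0.0) ? 1.0 : 0.0);
      break;
    case OP_OR:
      if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a != 0.0 || b != 0.0) ? 1.0 : 0.0);
      break;
    case OP_NOT:
      if (pop_d(L, a)) push_d(V, L, (a == 0.0) ? 1.0 : 0.0);
      break;
    case OP_SWAP: {
      uint64_t w1, w2;
      if (!pop_w(L, w1) || !pop_w(L, w2)) return;
      push_w(V, L, w1);
      push_w(V, L, w2);
      break;
    }

    case OP_MALLOC: {
      if (!pop_d(L, a)) return;
      int64_t count;
      if (!as_index(a, 0, V.heap_words, count)) { lane_fault(L, "MALLOC invalid size"); return; }
      if (L.hp + count > V.heap_words) { lane_fault(L, "heap exhausted"); return; }
      L.allocs.push_back({L.hp, count, true});
      push_d(V, L, (double)L.hp);
      L.hp += count;
      break;
    }
    case OP_FREE: {
      if (!pop_d(L, a)) return;
      int64_t off;
      if (!as_index(a, 0, V.heap_words, off)) { lane_fault(L, "FREE invalid handle"); return; }
      for (size_t k = 0; k < L.allocs.size(); ++k) {
        if (L.allocs[k].off == off && L.allocs[k].live) { L.allocs[k].live = false; return; }
      }
      lane_fault(L, "FREE on non-live handle");
      break;
    }
    case OP_MEMCPY: {
      if (!pop_d(L, c) || !pop_d(L, b) || !pop_d(L, a)) return;  // count, src, dst
      int64_t count, src, dst;
      if (!as_index(c, 0, V.heap_words, count) ||
          !as_index(b, 0, V.heap_words, src) ||
          !as_index(a, 0, V.heap_words, dst) ||
          !heap_range_ok(L, src, count) || !heap_range_ok(L, dst, count)) {
        lane_fault(L, "MEMCPY range not within live allocations");
        return;
      }
      std::memmove(&L.heap[(size_t)dst], &L.heap[(size_t)src], (size_t)count * 8);
      break;
    }
    case OP_TERNARY: {
      uint64_t we, wt;
      if (!pop_w(L, we) || !pop_w(L, wt)) return;   // else (top), then
      if (!pop_d(L, c)) return;                      // cond
      push_w(V, L, (c != 0.0) ? wt : we);
      break;
    }

    case OP_EQ:   if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a == b) ? 1.0 : 0.0); break;
    case OP_NEQ:  if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a != b) ? 1.0 : 0.0); break;
    case OP_GT:   if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a > b) ? 1.0 : 0.0); break;
    case OP_LT:   if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a < b) ? 1.0 : 0.0); break;
    case OP_GTEQ: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a >= b) ? 1.0 : 0.0); break;
    case OP_LTEQ: if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, (a <= b) ? 1.0 : 0.0); break;

    case OP_PTR_DEREF: {
      if (!pop_d(L, a)) return;
      int64_t addr;
      if (!as_index(a, 0, V.heap_words, addr) || !heap_range_ok(L, addr, 1)) {
        lane_fault(L, "PTR_DEREF outside live allocation");
        return;
      }
      push_w(V, L, L.heap[(size_t)addr]);
      break;
    }
    case OP_PTR_STORE: {
      if (!pop_d(L, a)) return;  // address
      if (!pop_w(L, w)) return;  // value
      int64_t addr;
      if (!as_index(a, 0, V.heap_words, addr) || !heap_range_ok(L, addr, 1)) {
        lane_fault(L, "PTR_STORE outside live allocation");
        return;
      }
      L.heap[(size_t)addr] = w;
      break;
    }

    case OP_READ_F64: case OP_READ_F32: case OP_READ_I32: case OP_READ_CHAR: {
      if (!pop_d(L, a) || !pop_d(L, b)) return;  // buffer id (top), index
      int64_t bid, idx;
      if (!as_index(a, 0, (int64_t)V.env.size() - 1, bid)) {
        lane_fault(L, "invalid environment buffer id");
        return;
      }
      EnvBuf& buf = V.env[(size_t)bid];
      int want = (op == OP_READ_F64) ? T_F64 : (op == OP_READ_F32) ? T_F32 :
                 (op == OP_READ_I32) ? T_I32 : T_CHAR;
      if (buf.type != want) { lane_fault(L, "environment buffer type mismatch"); return; }
      if (!as_index(b, 0, (int64_t)buf.len() - 1, idx)) {
        lane_fault(L, "environment index out of range");
        return;
      }
      double v = (want == T_F64) ? buf.f64[(size_t)idx] :
                 (want == T_F32) ? (double)buf.f32[(size_t)idx] :
                 (want == T_I32) ? (double)buf.i32[(size_t)idx] :
                 (double)buf.ch[(size_t)idx];
      push_d(V, L, v);
      break;
    }
    case OP_WRITE_F64: case OP_WRITE_F32: case OP_WRITE_I32: case OP_WRITE_CHAR: {
      if (!pop_d(L, a) || !pop_d(L, b) || !pop_d(L, c)) return;  // bufid, index, value
      int64_t bid, idx;
      if (!as_index(a, 0, (int64_t)V.env.size() - 1, bid)) {
        lane_fault(L, "invalid environment buffer id");
        return;
      }
      EnvBuf& buf = V.env[(size_t)bid];
      int want = (op == OP_WRITE_F64) ? T_F64 : (op == OP_WRITE_F32) ? T_F32 :
                 (op == OP_WRITE_I32) ? T_I32 : T_CHAR;
      if (buf.type != want) { lane_fault(L, "environment buffer type mismatch"); return; }
      if (!as_index(b, 0, (int64_t)buf.len() - 1, idx)) {
        lane_fault(L, "environment index out of range");
        return;
      }
      if (want == T_F64) buf.f64[(size_t)idx] = c;
      else if (want == T_F32) buf.f32[(size_t)idx] = (float)c;
      else if (want == T_I32) {
        double t = std::trunc(c);
        if (!std::isfinite(t) || t < -2147483648.0 || t > 2147483647.0) {
          lane_fault(L, "WRITE_I32 value outside int32 range");
          return;
        }
        buf.i32[(size_t)idx] = (int32_t)t;
      } else {
        double t = std::trunc(c);
        if (!std::isfinite(t) || t < 0.0 || t > 255.0) {
          lane_fault(L, "WRITE_CHAR value outside byte range");
          return;
        }
        buf.ch[(size_t)idx] = (uint8_t)t;
      }
      break;
    }

    case OP_ACOS:  if (pop_d(L, a)) push_d(V, L, std::acos(a)); break;
    case OP_ASIN:  if (pop_d(L, a)) push_d(V, L, std::asin(a)); break;
    case OP_ATAN:  if (pop_d(L, a)) push_d(V, L, std::atan(a)); break;
    case OP_SIN:   if (pop_d(L, a)) push_d(V, L, std::sin(a)); break;
    case OP_COS:   if (pop_d(L, a)) push_d(V, L, std::cos(a)); break;
    case OP_TAN:   if (pop_d(L, a)) push_d(V, L, std::tan(a)); break;
    case OP_SQRT:  if (pop_d(L, a)) push_d(V, L, std::sqrt(a)); break;
    case OP_LOG:   if (pop_d(L, a)) push_d(V, L, std::log(a)); break;
    case OP_EXP:   if (pop_d(L, a)) push_d(V, L, std::exp(a)); break;
    case OP_ERF:   if (pop_d(L, a)) push_d(V, L, std::erf(a)); break;
    case OP_ABS:   if (pop_d(L, a)) push_d(V, L, std::fabs(a)); break;
    case OP_FLOOR: if (pop_d(L, a)) push_d(V, L, std::floor(a)); break;
    case OP_POW:   if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, std::pow(a, b)); break;
    case OP_FMOD:  // truncated-division remainder: a - trunc(a/b) * b
      if (pop_d(L, b) && pop_d(L, a)) push_d(V, L, a - std::trunc(a / b) * b);
      break;

    case OP_PRINTC: {
      if (!pop_d(L, a)) return;
      double t = std::trunc(a);
      if (!std::isfinite(t) || t < 0.0 || t > 255.0) {
        lane_fault(L, "PRINTC value outside byte range");
        return;
      }
      V.console += (char)(uint8_t)t;
      break;
    }
    case OP_PRINTF:
      if (!pop_d(L, a)) return;
      append_printf(V, a);
      break;

    case OP_DOUBLETOLONGLONG: {
      if (!pop_d(L, a)) return;
      // round-to-nearest value conversion, stored as a raw int64 word
      if (!std::isfinite(a) || a < -9.2233720368547758e18 || a > 9.2233720368547758e18) {
        lane_fault(L, "DOUBLETOLONGLONG value out of range");
        return;
      }
      push_w(V, L, i2w((int64_t)std::llround(a)));
      break;
    }
    case OP_LONGLONGTODOUBLE:
      if (!pop_w(L, w)) return;
      push_d(V, L, (double)w2i(w));
      break;

    case OP_LDPC:      push_d(V, L, (double)pc_cur); break;
    case OP_LDTID:     push_d(V, L, (double)L.tid); break;
    case OP_LDSTK_PTR: push_d(V, L, (double)L.sp); break;

    case OP_SYNCWARP:  L.status = ST_BLOCKED; L.barrier = 0; break;
    case OP_SYNCBLOCK: L.status = ST_BLOCKED; L.barrier = 1; break;
    case OP_SYNCGRID:  L.status = ST_BLOCKED; L.barrier = 2; break;

    default:
      lane_fault(L, "unknown operation id");
  }
}

// one instruction on one lane
static void step_lane(Vm& V, Lane& L) {
  int64_t pc = L.pc;
  if (pc < 0 || pc >= V.n()) { lane_fault(L, "program counter out of range"); return; }
  int ins = V.instr[(size_t)pc];
  double d;
  switch (ins) {
    case I_VALUE:
      L.pc = pc + 1;
      push_d(V, L, V.vals[(size_t)pc]);
      break;
    case I_OP:
      L.pc = pc + 1;
      if (V.ops[(size_t)pc] < 0) { lane_fault(L, "null operation slot"); return; }
      exec_op(V, L, V.ops[(size_t)pc], pc);
      break;
    case I_SI_VALUE_OP:
      L.pc = pc + 1;
      if (V.ops[(size_t)pc] < 0) { lane_fault(L, "null operation slot"); return; }
      if (!push_d(V, L, V.vals[(size_t)pc])) return;
      exec_op(V, L, V.ops[(size_t)pc], pc);
      break;
    case I_SI_OP_VALUE:
      L.pc = pc + 1;
      if (V.ops[(size_t)pc] < 0) { lane_fault(L, "null operation slot"); return; }
      exec_op(V, L, V.ops[(size_t)pc], pc);
      if (L.status == ST_RUNNING || L.status == ST_BLOCKED)
        push_d(V, L, V.vals[(size_t)pc]);
      break;
    case I_JUMP: {
      if (!pop_d(L, d)) return;
      int64_t tgt;
      if (!as_index(d, 0, V.n(), tgt)) { lane_fault(L, "jump target invalid"); return; }
      L.pc = tgt;
      break;
    }
    case I_JUMPIFZERO: {
      double cond;
      if (!pop_d(L, d)) return;      // target on top
      if (!pop_d(L, cond)) return;   // condition beneath
      if (cond == 0.0) {
        int64_t tgt;
        if (!as_index(d, 0, V.n(), tgt)) { lane_fault(L, "jump target invalid"); return; }
        L.pc = tgt;
      } else {
        L.pc = pc + 1;
      }
      break;
    }
    default:
      lane_fault(L, "unknown instruction code");
  }
  if (L.status == ST_RUNNING && L.pc == V.n()) L.status = ST_HALTED;
}

// Barrier resolution.  A scope's members all have to be blocked at the same
// scope before release; if no member can still run but not all arrived, the
// waiting lanes fault with a deadlock.
static void resolve_barriers(Vm& V) {
  int nl = (int)V.lanes.size();
  for (int scope = 0; scope <= 2; ++scope) {
    // group lanes: warp = contiguous warp_size blocks, block/grid = all lanes
    int ngroups = (scope == 0) ? (nl + V.warp_size - 1) / V.warp_size : 1;
    for (int g = 0; g < ngroups; ++g) {
      int lo = (scope == 0) ? g * V.warp_size : 0;
      int hi = (scope == 0) ? std::min(nl, lo + V.warp_size) : nl;
      bool any_blocked_here = false, any_running = false, all_blocked_here = true;
      for (int i = lo; i < hi; ++i) {
        Lane& L = V.lanes[(size_t)i];
        if (L.status == ST_BLOCKED && L.barrier == scope) any_blocked_here = true;
        else all_blocked_here = false;
        if (L.status == ST_RUNNING ||
            (L.status == ST_BLOCKED && L.barrier != scope)) any_running = true;
      }
      if (!any_blocked_here) continue;
      if (all_blocked_here) {
        for (int i = lo; i < hi; ++i) {
          V.lanes[(size_t)i].status = ST_RUNNING;
          V.lanes[(size_t)i].barrier = -1;
        }
      } else if (!any_running) {
        for (int i = lo; i < hi; ++i) {
          Lane& L = V.lanes[(size_t)i];
          if (L.status == ST_BLOCKED && L.barrier == scope)
            lane_fault(L, "barrier deadlock");
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// R interface

static int type_code(const std::string& t) {
  if (t == "f64") return T_F64;
  if (t == "f32") return T_F32;
  if (t == "i32") return T_I32;
  if (t == "char") return T_CHAR;
  stop("unknown environment buffer type '%s'", t.c_str());
  return -1;
}

// [[Rcpp::export]]
DataFrame cpp_op_table() {
  int n = OP__COUNT;
  CharacterVector name(n), category(n);
  IntegerVector id(n), ain(n), aout(n);
  for (int i = 0; i < n; ++i) {
    id[i] = i;
    name[i] = OP_TABLE[i].name;
    category[i] = OP_TABLE[i].category;
    ain[i] = OP_TABLE[i].in;
    aout[i] = OP_TABLE[i].out;
  }
  return DataFrame::create(_["id"] = id, _["name"] = name, _["category"] = category,
                           _["arity_in"] = ain, _["arity_out"] = aout,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
SEXP cpp_vm_load(IntegerVector instr, IntegerVector ops, NumericVector vals,
                 CharacterVector env_names, CharacterVector env_types,
                 List env_values, int n_lanes,
                 double stack_capacity, double heap_words, double max_steps,
                 int warp_size) {
  if (n_lanes < 1) stop("n_lanes must be >= 1");
  if (stack_capacity < 1) stop("stack_capacity must be >= 1");
  if (heap_words < 0) stop("heap_words must be >= 0");
  if (warp_size < 1) stop("warp_size must be >= 1");
  Vm* V = new Vm();
  V->instr.assign(instr.begin(), instr.end());
  V->ops.assign(ops.begin(), ops.end());
  V->vals.assign(vals.begin(), vals.end());
  V->stack_cap = (int64_t)stack_capacity;
  V->heap_words = (int64_t)heap_words;
  V->max_steps = (int64_t)max_steps;
  V->warp_size = warp_size;
  int ne = env_names.size();
  for (int i = 0; i < ne; ++i) {
    EnvBuf b;
    b.name = as<std::string>(env_names[i]);
    b.type = type_code(as<std::string>(env_types[i]));
    if (b.type == T_F64) {
      NumericVector v = env_values[i];
      b.f64.assign(v.begin(), v.end());
    } else if (b.type == T_F32) {
      NumericVector v = env_values[i];
      b.f32.resize(v.size());
      for (int j = 0; j < v.size(); ++j) b.f32[(size_t)j] = (float)v[j];
    } else if (b.type == T_I32) {
      IntegerVector v = env_values[i];
      b.i32.assign(v.begin(), v.end());
    } else {
      RawVector v = env_values[i];
      b.ch.assign(v.begin(), v.end());
    }
    V->env.push_back(b);
  }
  V->lanes.resize((size_t)n_lanes);
  for (int i = 0; i < n_lanes; ++i) {
    Lane& L = V->lanes[(size_t)i];
    L.tid = i;
    L.stack.resize((size_t)V->stack_cap, 0);
    L.heap.resize((size_t)V->heap_words, 0);
    if (V->n() == 0) L.status = ST_HALTED;
  }
  XPtr<Vm> p(V, true);
  return p;
}

static List lane_state(const Vm& V, const Lane& L) {
  NumericVector st((R_xlen_t)L.sp);
  for (int64_t i = 0; i < L.sp; ++i) st[(R_xlen_t)i] = w2d(L.stack[(size_t)i]);
  return List::create(
    _["pc"] = (double)L.pc, _["tid"] = L.tid, _["sp"] = (double)L.sp,
    _["stack"] = st, _["status"] = std::string(STATUS_NAMES[L.status]),
    _["fault"] = L.fault_reason, _["steps"] = (double)L.steps);
}

// [[Rcpp::export]]
List cpp_vm_lane(SEXP vmp, int lane) {
  XPtr<Vm> V(vmp);
  if (lane < 0 || lane >= (int)V->lanes.size()) stop("lane id out of range");
  return lane_state(*V, V->lanes[(size_t)lane]);
}

// [[Rcpp::export]]
List cpp_vm_step(SEXP vmp, int lane) {
  XPtr<Vm> V(vmp);
  if (lane < 0 || lane >= (int)V->lanes.size()) stop("lane id out of range");
  Lane& L = V->lanes[(size_t)lane];
  if (L.status != ST_RUNNING) stop("lane %d is not running", lane);
  step_lane(*V, L);
  L.steps++;
  if (L.status == ST_BLOCKED) resolve_barriers(*V);
  return lane_state(*V, L);
}

static List env_snapshot(const Vm& V) {
  int ne = (int)V.env.size();
  List out(ne);
  CharacterVector nm(ne);
  for (int i = 0; i < ne; ++i) {
    const EnvBuf& b = V.env[(size_t)i];
    nm[i] = b.name;
    if (b.type == T_F64) {
      out[i] = NumericVector(b.f64.begin(), b.f64.end());
    } else if (b.type == T_F32) {
      NumericVector v((R_xlen_t)b.f32.size());
      for (size_t j = 0; j < b.f32.size(); ++j) v[(R_xlen_t)j] = (double)b.f32[j];
      out[i] = v;
    } else if (b.type == T_I32) {
      out[i] = IntegerVector(b.i32.begin(), b.i32.end());
    } else {
      RawVector v((R_xlen_t)b.ch.size());
      for (size_t j = 0; j < b.ch.size(); ++j) v[(R_xlen_t)j] = b.ch[j];
      out[i] = v;
    }
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
List cpp_vm_run(SEXP vmp) {
  XPtr<Vm> V(vmp);
  int nl = (int)V->lanes.size();
  int64_t rounds = 0;
  for (;;) {
    bool running = false, blocked = false;
    for (int i = 0; i < nl; ++i) {
      Lane& L = V->lanes[(size_t)i];
      if (L.status == ST_RUNNING) {
        step_lane(*V, L);
        L.steps++;
        if (L.status == ST_RUNNING && L.steps >= V->max_steps) L.status = ST_STEPLIMIT;
      }
    }
    for (int i = 0; i < nl; ++i) {
      if (V->lanes[(size_t)i].status == ST_BLOCKED) blocked = true;
    }
    if (blocked) resolve_barriers(*V);
    running = false; blocked = false;
    for (int i = 0; i < nl; ++i) {
      int s = V->lanes[(size_t)i].status;
      if (s == ST_RUNNING) running = true;
      if (s == ST_BLOCKED) blocked = true;
    }
    if (!running) {
      if (blocked) {
        // nothing can make progress; resolve_barriers() has already faulted
        // genuinely deadlocked scopes, but mixed-scope waits are faulted here
        for (int i = 0; i < nl; ++i) {
          Lane& L = V->lanes[(size_t)i];
          if (L.status == ST_BLOCKED) lane_fault(L, "barrier deadlock");
        }
      }
      break;
    }
    if ((++rounds & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  V->finished = true;
  NumericVector steps(nl);
  CharacterVector status(nl), fault(nl);
  for (int i = 0; i < nl; ++i) {
    const Lane& L = V->lanes[(size_t)i];
    steps[i] = (double)L.steps;
    status[i] = STATUS_NAMES[L.status];
    fault[i] = L.fault_reason;
  }
  return List::create(
    _["steps"] = steps, _["status"] = status, _["fault"] = fault,
    _["console"] = V->console, _["env"] = env_snapshot(*V));
}

// [[Rcpp::export]]
List cpp_vm_env(SEXP vmp) {
  XPtr<Vm> V(vmp);
  return env_snapshot(*V);
}

// [[Rcpp::export]]
std::string cpp_vm_console(SEXP vmp) {
  XPtr<Vm> V(vmp);
  return V->console;
}
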