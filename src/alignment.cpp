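#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment of a junction probe against a transcript, linear gap
// penalty (each gapped base costs `gap`). 'N' never matches: an N column
// scores as a mismatch and is never counted in `matches`.
//
// Tie-breaks among co-optimal alignments: maximise matches, then smallest
// start position in the target. Cells with running score exactly 0 keep
// their non-empty alignment (a zero-score prefix can add matches to a
// co-optimal alignment); only negative-score cells reset, which preserves
// the exchange argument that makes the cell-local tie-breaks globally exact.

static inline bool is_match(char a, char b) {
    return a == b && a != 'N' && a != 'n';
}

// Cell state is packed into one comparable 64-bit key so the three-level
// tie-break (score, then matches, then smallest target start) is a single
// integer comparison:
//   bits 44..63  score + BIAS   (BIAS absorbs transiently negative scores)
//   bits 24..43  matches
//   bits  0..23  TMAX - target_start (smaller start = larger key)
// Auxiliary arrays carry aligned-column count and probe start for the
// reported alignment; cols == 0 marks the empty alignment.
static const int64_t BIAS = 1 << 12;
static const int64_t TMAX = (1 << 24) - 1;
static const int64_t K_SCORE = (int64_t)1 << 44;
static const int64_t K_MATCH = (int64_t)1 << 24;

// [[Rcpp::export]]
List sw_align_cpp(std::string probe, std::string target,
                  int match, int mismatch, int gap) {
    const int m = probe.size(), n = target.size();
    if (m == 0) stop("empty probe");
    if (n == 0) stop("empty target");
    if (m >= 1 << 19 || n >= 1 << 23) stop("sequence too long");

    const int64_t EMPTY = BIAS * K_SCORE + TMAX;  // score 0, matches 0
    std::vector<int64_t> kprev(n + 1, EMPTY), kcur(n + 1, EMPTY);
    std::vector<int> cprev(n + 1, 0), ccur(n + 1, 0);   // aligned columns
    std::vector<int> pprev(n + 1, 0), pcur(n + 1, 0);   // probe start

    int64_t gbest = EMPTY;
    int gcols = 0, gpstart = 0, gpend = 0, gtend = 0;
    const char *P = probe.c_str(), *T = target.c_str();

    for (int i = 1; i <= m; ++i) {
        kcur[0] = EMPTY; ccur[0] = 0; pcur[0] = 0;
        const char pc = P[i - 1];
        for (int j = 1; j <= n; ++j) {
            const bool mt = is_match(pc, T[j - 1]);
            const int sub = mt ? match : mismatch;

            int64_t best = EMPTY; int bc = 0, bp = 0;
            if (sub > 0) {  // fresh single-column alignment at (i, j)
                best = (sub + BIAS) * K_SCORE + K_MATCH + (TMAX - j);
                bc = 1; bp = i;
            }
            if (cprev[j - 1] > 0) {  // extend diagonally
                int64_t k = kprev[j - 1] + (int64_t)sub * K_SCORE +
                            (mt ? K_MATCH : 0);
                if ((k >> 44) >= BIAS && k > best) {
                    best = k; bc = cprev[j - 1] + 1; bp = pprev[j - 1];
                }
            }
            if (cprev[j] > 0) {  // gap in target, consume probe base
                int64_t k = kprev[j] + (int64_t)gap * K_SCORE;
                if ((k >> 44) >= BIAS && k > best) {
                    best = k; bc = cprev[j] + 1; bp = pprev[j];
                }
            }
            if (ccur[j - 1] > 0) {  // gap in probe, consume target base
                int64_t k = kcur[j - 1] + (int64_t)gap * K_SCORE;
                if ((k >> 44) >= BIAS && k > best) {
                    best = k; bc = ccur[j - 1] + 1; bp = pcur[j - 1];
                }
            }
            kcur[j] = best; ccur[j] = bc; pcur[j] = bp;
            if (bc > 0 && best > gbest) {
                gbest = best; gcols = bc; gpstart = bp;
                gpend = i; gtend = j;
            }
        }
        std::swap(kprev, kcur);
        std::swap(cprev, ccur);
        std::swap(pprev, pcur);
    }

    const int score = (int)((gbest >> 44) - BIAS);
    const int matches = (int)((gbest >> 24) & ((1 << 20) - 1));
    const int tstart = gcols > 0 ? (int)(TMAX - (gbest & TMAX)) : 0;
    return List::create(
        _["score"] = score,
        _["matches"] = matches,
        _["aligned_columns"] = gcols,
        _["probe_start"] = gpstart, _["probe_end"] = gpend,
        _["target_start"] = tstart, _["target_end"] = gtend);
}

// Exhaustive reference aligner used only for validation at tiny sizes.
// A local alignment under a linear gap penalty is fully determined by its
// ordered set of aligned residue pairs; this enumerates every monotone
// matching between subsequences of probe and target and scores it directly,
// applying the same tie-breaks as sw_align_cpp. Algorithmically independent
// of the dynamic program above (enumeration, no recurrences shared).

struct Enum {
    const std::string *a, *b;
    int match, mismatch, gap;
    int best_score, best_matches, best_cols, best_tstart;

    void consider(int score, int matches, int cols, int tstart) {
        if (score > best_score ||
            (score == best_score &&
             (matches > best_matches ||
              (matches == best_matches &&
               (best_cols == 0 || tstart < best_tstart))))) {
            best_score = score; best_matches = matches;
            best_cols = cols; best_tstart = tstart;
        }
    }

    void rec(int i, int j, int score, int matches, int cols, int tstart) {
        consider(score, matches, cols, tstart);
        const int m = a->size(), n = b->size();
        for (int i2 = i + 1; i2 <= m; ++i2) {
            for (int j2 = j + 1; j2 <= n; ++j2) {
                const bool mt = is_match((*a)[i2 - 1], (*b)[j2 - 1]);
                const int interior = (i2 - i - 1) + (j2 - j - 1);
                rec(i2, j2,
                    score + (mt ? match : mismatch) + gap * interior,
                    matches + (mt ? 1 : 0),
                    cols + 1 + interior, tstart);
            }
        }
    }
};

// [[Rcpp::export]]
List sw_enumerate_cpp(std::string probe, std::string target,
                      int match, int mismatch, int gap) {
    const int m = probe.size(), n = target.size();
    if (m == 0) stop("empty probe");
    if (m > 10 || n > 16) stop("exhaustive aligner is limited to tiny inputs");

    Enum e{&probe, &target, match, mismatch, gap, 0, 0, 0, 0};
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            const bool mt = is_match(probe[i - 1], target[j - 1]);
            e.rec(i, j, mt ? match : mismatch, mt ? 1 : 0, 1, j);
        }
    }
    if (e.best_score <= 0) { e.best_score = 0; e.best_matches = 0; e.best_cols = 0; e.best_tstart = 0; }
    return List::create(
        _["score"] = e.best_score,
        _["matches"] = e.best_matches,
        _["aligned_columns"] = e.best_cols,
        _["target_start"] = e.best_tstart);
}
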