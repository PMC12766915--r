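#include <Rcpp.h>
#include <vector>
#include <map>
#include <climits>
#include <algorithm>
#include <cmath>
#include "ivh_util.h"

using namespace Rcpp;

// Simplified single-pass colinear chaining over anchors of one
// (query, target, relative-strand) triple, standing in for minimap2's chainer
// as a fixed, seed-mode-agnostic harness.
//
// Anchors carry end-standardized positions in original coordinates.  For
// reverse-strand anchor sets the query axis is flipped (q' = qlen - 1 - qpos)
// so that colinear chains are increasing on both axes; emitted PAF coordinates
// always refer to the original (forward) query.
//
// score(j <- i) = score(i) + min(span_j, qdiff, tdiff) - gamma * |qdiff - tdiff|
// with qdiff, tdiff in (0, G].  Chains scoring >= min_score are emitted.
// residue_matches = first anchor span + per-step min(span, qdiff, tdiff);
// block_len = max(query extent, target extent); mapq is not computed (0).

struct AnchorOrd { int q, t, qorig, span; };

// [[Rcpp::export(name = ".cpp_chain")]]
DataFrame cpp_chain(IntegerVector qpos, IntegerVector tpos, IntegerVector span,
                    bool rev, int qlen, int tlen,
                    double max_gap, double gamma, double min_score,
                    int lookback) {
    const int n = qpos.size();
    if (tpos.size() != n || span.size() != n)
        stop("qpos, tpos, span must have equal length");
    std::vector<AnchorOrd> a(n);
    for (int i = 0; i < n; ++i) {
        a[i].qorig = qpos[i];
        a[i].q = rev ? (qlen - 1 - qpos[i]) : qpos[i];
        a[i].t = tpos[i];
        a[i].span = span[i];
    }
    std::sort(a.begin(), a.end(), [](const AnchorOrd& x, const AnchorOrd& y) {
        return x.t != y.t ? x.t < y.t : x.q < y.q;
    });
    std::vector<double> f(n);
    std::vector<int> pred(n, -1);
    for (int j = 0; j < n; ++j) {
        f[j] = a[j].span;
        int lb = 0;
        for (int i = j - 1; i >= 0 && lb < lookback; --i, ++lb) {
            double td = (double)a[j].t - a[i].t;
            if (td > max_gap) break;               // sorted by t
            if (td <= 0) continue;
            double qd = (double)a[j].q - a[i].q;
            if (qd <= 0 || qd > max_gap) continue;
            double inc = std::min((double)a[j].span, std::min(qd, td));
            double sc = f[i] + inc - gamma * std::fabs(qd - td);
            if (sc > f[j]) { f[j] = sc; pred[j] = i; }
        }
    }
    // extract chains greedily by terminal score; anchors are used once
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int x, int y) { return f[x] > f[y]; });
    std::vector<char> used(n, 0);
    std::vector<double> o_score;
    std::vector<int> o_qs, o_qe, o_ts, o_te, o_match, o_block, o_n;
    for (int oi = 0; oi < n; ++oi) {
        int end = ord[oi];
        if (used[end]) continue;
        std::vector<int> chain;
        int cur = end;
        while (cur != -1 && !used[cur]) {
            chain.push_back(cur);
            cur = pred[cur];
        }
        double base = (cur == -1) ? 0.0 : f[cur];
        double score = f[end] - base;
        if (score < min_score) continue;
        std::reverse(chain.begin(), chain.end());  // increasing t
        for (int c : chain) used[c] = 1;
        int qlo = INT_MAX, qhi = INT_MIN, tlo = INT_MAX, thi = INT_MIN;
        double match = a[chain[0]].span;
        for (size_t ci = 0; ci < chain.size(); ++ci) {
            const AnchorOrd& an = a[chain[ci]];
            qlo = std::min(qlo, an.qorig - an.span + 1);
            qhi = std::max(qhi, an.qorig + 1);
            tlo = std::min(tlo, an.t - an.span + 1);
            thi = std::max(thi, an.t + 1);
            if (ci > 0) {
                const AnchorOrd& pv = a[chain[ci - 1]];
                double qd = std::fabs((double)an.qorig - pv.qorig);
                double td = (double)an.t - pv.t;
                match += std::min((double)an.span, std::min(qd, td));
            }
        }
        o_qs.push_back(qlo); o_qe.push_back(qhi);
        o_ts.push_back(tlo); o_te.push_back(thi);
        o_match.push_back((int)std::lround(match));
        o_block.push_back(std::max(qhi - qlo, thi - tlo));
        o_score.push_back(score);
        o_n.push_back((int)chain.size());
    }
    return DataFrame::create(
        _["qstart"] = IntegerVector(o_qs.begin(), o_qs.end()),
        _["qend"] = IntegerVector(o_qe.begin(), o_qe.end()),
        _["tstart"] = IntegerVector(o_ts.begin(), o_ts.end()),
        _["tend"] = IntegerVector(o_te.begin(), o_te.end()),
        _["matches"] = IntegerVector(o_match.begin(), o_match.end()),
        _["block_len"] = IntegerVector(o_block.begin(), o_block.end()),
        _["score"] = NumericVector(o_score.begin(), o_score.end()),
        _["n_anchors"] = IntegerVector(o_n.begin(), o_n.end()));
}

// Streaming anchor/offset statistics over many read pairs, used for
// dotplot-style off-diagonal quantification without materialising anchors.
// For each pair: anchors are equal-key seed pairs; the offset of a same-strand
// anchor is posA - posB, of an opposite-strand anchor posA + posB (constant
// along an antidiagonal).  Offsets are binned at `band` bases; the modal bin
// (over both strand classes) defines the principal diagonal, and anchors
// outside modal bin +/- 1 in that strand class count as off-diagonal.
// [[Rcpp::export(name = ".cpp_pair_offset_stats")]]
DataFrame cpp_pair_offset_stats(List keys, List pos, List strand,
                                IntegerMatrix pairs, double band) {
    const int nread = keys.size();
    if (pos.size() != nread || strand.size() != nread)
        stop("keys, pos, strand lists must have equal length");
    if (band <= 0) stop("band must be > 0");
    // parse + sort each read's seeds by key once
    std::vector<std::vector<uint64_t>> K(nread);
    std::vector<std::vector<int>> P(nread);
    std::vector<std::vector<char>> S(nread);
    for (int r = 0; r < nread; ++r) {
        CharacterVector kv = keys[r];
        IntegerVector pv = pos[r];
        CharacterVector sv = strand[r];
        const int m = kv.size();
        if (pv.size() != m || sv.size() != m)
            stop("per-read seed vectors must have equal length");
        std::vector<int> idx(m);
        std::vector<uint64_t> kk(m);
        for (int i = 0; i < m; ++i) {
            kk[i] = ivh_from_hex(String(kv[i]).get_cstring());
            idx[i] = i;
        }
        std::sort(idx.begin(), idx.end(),
                  [&](int x, int y) { return kk[x] < kk[y]; });
        K[r].resize(m); P[r].resize(m); S[r].resize(m);
        for (int i = 0; i < m; ++i) {
            K[r][i] = kk[idx[i]];
            P[r][i] = pv[idx[i]];
            S[r][i] = *String(sv[idx[i]]).get_cstring();
        }
    }
    const int np = pairs.nrow();
    NumericVector total(np), offdiag(np);
    for (int p = 0; p < np; ++p) {
        int ra = pairs(p, 0) - 1, rb = pairs(p, 1) - 1;
        if (ra < 0 || ra >= nread || rb < 0 || rb >= nread)
            stop("pair index out of range");
        std::map<long long, double> histF, histR;
        double tot = 0;
        size_t i = 0, j = 0;
        const size_t na = K[ra].size(), nb = K[rb].size();
        while (i < na && j < nb) {
            if (K[ra][i] < K[rb][j]) { ++i; continue; }
            if (K[ra][i] > K[rb][j]) { ++j; continue; }
            size_t i2 = i, j2 = j;
            while (i2 < na && K[ra][i2] == K[ra][i]) ++i2;
            while (j2 < nb && K[rb][j2] == K[rb][j]) ++j2;
            for (size_t x = i; x < i2; ++x)
                for (size_t y = j; y < j2; ++y) {
                    bool same = S[ra][x] == S[rb][y];
                    double off = same ? (double)P[ra][x] - P[rb][y]
                                      : (double)P[ra][x] + P[rb][y];
                    long long bin = (long long)std::floor(off / band);
                    (same ? histF : histR)[bin] += 1.0;
                    tot += 1.0;
                }
            i = i2; j = j2;
        }
        // modal bin across both strand classes
        double best = -1; long long bbin = 0; bool bfwd = true;
        for (auto& kvp : histF)
            if (kvp.second > best) { best = kvp.second; bbin = kvp.first; bfwd = true; }
        for (auto& kvp : histR)
            if (kvp.second > best) { best = kvp.second; bbin = kvp.first; bfwd = false; }
        double inband = 0;
        if (best > 0) {
            std::map<long long, double>& h = bfwd ? histF : histR;
            for (long long b = bbin - 1; b <= bbin + 1; ++b) {
                auto it = h.find(b);
                if (it != h.end()) inband += it->second;
            }
        }
        total[p] = tot;
        offdiag[p] = tot - inband;
    }
    return DataFrame::create(_["total"] = total, _["offdiag"] = offdiag);
}
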