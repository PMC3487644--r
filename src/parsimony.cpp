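// Core parsimony engine: Fitch scoring on unrooted binary trees,
// stepwise addition, NNI/SPR/TBR branch swapping with equal-best tree
// collection, and exact branch-and-bound enumeration of all
// most-parsimonious trees.
//
// Internal tree representation: an unrooted binary tree over nTip
// terminals is an edge list on node ids 0..(2*nTip-3), where ids
// 0..nTip-1 are terminals and the rest are internal (degree 3).
// Character states are bitmasks (bit k = state k), so missing /
// inapplicable / polymorphic cells are just wider masks.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <cstdio>
#include <vector>
#include <deque>
#include <functional>
#include <set>
#include <map>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  // parallel arrays of edge endpoints
  std::vector<int> a, b;
  int nedge() const { return (int)a.size(); }
  void add(int x, int y) { a.push_back(x); b.push_back(y); }
};

struct Engine {
  int nTip, nChar;
  std::vector<uint32_t> tip;  // nTip * nChar, row-major by tip

  // scratch buffers sized for full trees
  std::vector<std::vector<int>> adj;
  std::vector<int> post, parent, stack_;
  std::vector<uint32_t> state;

  Engine(int nTip_, int nChar_, const IntegerMatrix& tipStates)
      : nTip(nTip_), nChar(nChar_) {
    tip.resize((size_t)nTip * nChar);
    for (int t = 0; t < nTip; ++t)
      for (int c = 0; c < nChar; ++c)
        tip[(size_t)t * nChar + c] = (uint32_t)tipStates(t, c);
    int maxNode = 2 * nTip;  // slack for one transient node
    adj.assign(maxNode, {});
    parent.assign(maxNode, -1);
    state.resize((size_t)maxNode * nChar);
  }

  // Build adjacency and a postorder rooted at terminal `root`.
  // Returns false if the tree is disconnected (should not happen).
  void buildPostorder(const Tree& tr, int root) {
    int maxNode = 0;
    for (int i = 0; i < tr.nedge(); ++i)
      maxNode = std::max(maxNode, std::max(tr.a[i], tr.b[i]));
    for (int v = 0; v <= maxNode; ++v) adj[v].clear();
    for (int i = 0; i < tr.nedge(); ++i) {
      adj[tr.a[i]].push_back(tr.b[i]);
      adj[tr.b[i]].push_back(tr.a[i]);
    }
    post.clear();
    stack_.clear();
    stack_.push_back(root);
    parent[root] = -1;
    while (!stack_.empty()) {
      int v = stack_.back();
      stack_.pop_back();
      post.push_back(v);
      for (int w : adj[v])
        if (w != parent[v]) {
          parent[w] = v;
          stack_.push_back(w);
        }
    }
    std::reverse(post.begin(), post.end());  // children before parents
  }

  // Fitch length over all characters, rooted at terminal `root`.
  // If bound >= 0, returns early with a value > bound once exceeded.
  // If perChar != NULL it is filled with per-character step counts
  // (no early exit in that case).
  int fitch(const Tree& tr, int root, int bound = -1,
            std::vector<int>* perChar = nullptr) {
    buildPostorder(tr, root);
    if (perChar) perChar->assign(nChar, 0);
    int steps = 0;
    for (int v : post) {
      uint32_t* sv = &state[(size_t)v * nChar];
      if (v < nTip) {
        std::copy(tip.begin() + (size_t)v * nChar,
                  tip.begin() + (size_t)(v + 1) * nChar, sv);
        continue;
      }
      bool first = true;
      for (int w : adj[v]) {
        if (w == parent[v]) continue;
        const uint32_t* sw = &state[(size_t)w * nChar];
        if (first) {
          std::copy(sw, sw + nChar, sv);
          first = false;
        } else {
          for (int c = 0; c < nChar; ++c) {
            uint32_t inter = sv[c] & sw[c];
            if (inter) {
              sv[c] = inter;
            } else {
              sv[c] |= sw[c];
              ++steps;
              if (perChar) ++(*perChar)[c];
            }
          }
          if (bound >= 0 && steps > bound && !perChar) return steps;
        }
      }
    }
    // the root is a terminal: fold its own state set against its
    // single neighbour (the root edge is otherwise never counted)
    if (root < nTip) {
      const uint32_t* sr = &tip[(size_t)root * nChar];
      for (int w : adj[root]) {
        const uint32_t* sw = &state[(size_t)w * nChar];
        for (int c = 0; c < nChar; ++c)
          if ((sr[c] & sw[c]) == 0) {
            ++steps;
            if (perChar) ++(*perChar)[c];
          }
      }
    }
    return steps;
  }

  // Bipartition signature: sorted masks of the non-trivial splits,
  // each normalised to exclude tip 0.  Requires nTip <= 64.
  std::vector<uint64_t> signature(const Tree& tr) {
    buildPostorder(tr, 0);
    std::vector<uint64_t> below(2 * nTip, 0);
    std::vector<uint64_t> sig;
    uint64_t all = (nTip == 64) ? ~0ULL : ((1ULL << nTip) - 1);
    for (int v : post) {
      if (v < nTip) {
        below[v] = 1ULL << v;
      } else {
        uint64_t m = 0;
        for (int w : adj[v])
          if (w != parent[v]) m |= below[w];
        below[v] = m;
        int pc = 0;
        uint64_t mm = m;
        while (mm) { mm &= mm - 1; ++pc; }
        if (pc >= 2 && pc <= nTip - 2) {
          uint64_t s = (m & 1ULL) ? (all & ~m) : m;
          sig.push_back(s);
        }
      }
    }
    std::sort(sig.begin(), sig.end());
    return sig;
  }
};

// Relabel internal nodes to nTip..2*nTip-3 in discovery order from tip 0.
Tree normalize(const Tree& tr, int nTip) {
  int maxNode = 0;
  for (int i = 0; i < tr.nedge(); ++i)
    maxNode = std::max(maxNode, std::max(tr.a[i], tr.b[i]));
  std::vector<std::vector<std::pair<int, int>>> adj(maxNode + 1);
  for (int i = 0; i < tr.nedge(); ++i) {
    adj[tr.a[i]].push_back({tr.b[i], i});
    adj[tr.b[i]].push_back({tr.a[i], i});
  }
  std::vector<int> newid(maxNode + 1, -1);
  for (int t = 0; t < nTip; ++t) newid[t] = t;
  int next = nTip;
  std::vector<int> st{0};
  std::vector<char> seen(maxNode + 1, 0);
  seen[0] = 1;
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    if (newid[v] < 0) newid[v] = next++;
    for (auto& pw : adj[v])
      if (!seen[pw.first]) {
        seen[pw.first] = 1;
        st.push_back(pw.first);
      }
  }
  Tree out;
  for (int i = 0; i < tr.nedge(); ++i) out.add(newid[tr.a[i]], newid[tr.b[i]]);
  return out;
}

// Newick string with 1-based tip indices as labels, unrooted
// (basal trichotomy at the internal node adjacent to tip 0).
std::string toNewick(const Tree& tr, int nTip) {
  int maxNode = 0;
  for (int i = 0; i < tr.nedge(); ++i)
    maxNode = std::max(maxNode, std::max(tr.a[i], tr.b[i]));
  std::vector<std::vector<int>> adj(maxNode + 1);
  for (int i = 0; i < tr.nedge(); ++i) {
    adj[tr.a[i]].push_back(tr.b[i]);
    adj[tr.b[i]].push_back(tr.a[i]);
  }
  if (nTip == 1) return "1;";
  if (nTip == 2) return "(1,2);";
  int root = adj[0][0];  // internal neighbour of tip 0
  std::string s;
  // iterative DFS with explicit output building via recursion-free stack
  // (trees are tiny; plain recursion via lambda is fine)
  std::function<void(int, int)> rec = [&](int v, int par) {
    if (v < nTip) {
      s += std::to_string(v + 1);
      return;
    }
    s += '(';
    bool first = true;
    for (int w : adj[v]) {
      if (w == par) continue;
      if (!first) s += ',';
      first = false;
      rec(w, v);
    }
    s += ')';
  };
  s += '(';
  bool first = true;
  for (int w : adj[root]) {
    if (!first) s += ',';
    first = false;
    rec(w, root);
  }
  s += ");";
  return s;
}

// Parse an ape edge matrix (1-based, tips 1..nTip) into a Tree (0-based).
Tree fromEdgeMatrix(const IntegerMatrix& edge, int nTip) {
  // ape roots unrooted trees at node nTip+1 with a basal multifurcation;
  // node ids nTip+1.. are internal.  We keep ids as-is minus 1.
  Tree tr;
  for (int i = 0; i < edge.nrow(); ++i) tr.add(edge(i, 0) - 1, edge(i, 1) - 1);
  return tr;
}

// Insert terminal t on edge ei of tr using new internal node id `newNode`.
Tree insertTip(const Tree& tr, int ei, int t, int newNode) {
  Tree out = tr;
  int u = out.a[ei], v = out.b[ei];
  out.a[ei] = u;
  out.b[ei] = newNode;
  out.add(newNode, v);
  out.add(newNode, t);
  return out;
}

// Remove edge ei; returns the two fragments with degree-2 endpoints
// suppressed.  For each fragment, `attach` lists candidate reconnection
// points: non-negative values are edge indices into that fragment,
// and a single tip fragment is encoded as attach = {-1 - tipId}.
// `origAttach` records the reconnection point that restores the
// original tree (the merged edge, or the lone tip).
struct Fragment {
  Tree tr;
  std::vector<int> attach;
  int origAttach;
};

void bisect(const Tree& tr, int ei, int nTip, Fragment& A, Fragment& B) {
  int a0 = tr.a[ei], b0 = tr.b[ei];
  // component of a0 (excluding edge ei)
  int maxNode = 0;
  for (int i = 0; i < tr.nedge(); ++i)
    maxNode = std::max(maxNode, std::max(tr.a[i], tr.b[i]));
  std::vector<std::vector<std::pair<int, int>>> adj(maxNode + 1);
  for (int i = 0; i < tr.nedge(); ++i) {
    if (i == ei) continue;
    adj[tr.a[i]].push_back({tr.b[i], i});
    adj[tr.b[i]].push_back({tr.a[i], i});
  }
  std::vector<char> inA(maxNode + 1, 0);
  std::vector<int> st{a0};
  inA[a0] = 1;
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    for (auto& pw : adj[v])
      if (!inA[pw.first]) {
        inA[pw.first] = 1;
        st.push_back(pw.first);
      }
  }
  auto build = [&](int cut, bool takeA, Fragment& F) {
    F.tr = Tree();
    F.attach.clear();
    F.origAttach = -999;
    // collect edges of this side
    std::vector<int> eidx;
    for (int i = 0; i < tr.nedge(); ++i) {
      if (i == ei) continue;
      bool sideA = inA[tr.a[i]] != 0;
      if (sideA == takeA) eidx.push_back(i);
    }
    if (eidx.empty()) {
      // single-node fragment: the cut endpoint is a terminal
      F.attach.push_back(-1 - cut);
      F.origAttach = -1 - cut;
      return;
    }
    // suppress the cut endpoint if it is internal (degree 2 now)
    if (cut >= nTip) {
      int e1 = -1, e2 = -1;
      for (int i : eidx)
        if (tr.a[i] == cut || tr.b[i] == cut) {
          if (e1 < 0) e1 = i; else e2 = i;
        }
      int x = (tr.a[e1] == cut) ? tr.b[e1] : tr.a[e1];
      int y = (tr.a[e2] == cut) ? tr.b[e2] : tr.a[e2];
      for (int i : eidx) {
        if (i == e1) { F.tr.add(x, y); F.origAttach = F.tr.nedge() - 1; }
        else if (i == e2) continue;
        else F.tr.add(tr.a[i], tr.b[i]);
      }
    } else {
      for (int i : eidx) F.tr.add(tr.a[i], tr.b[i]);
      F.origAttach = -1 - cut;  // terminal cut endpoint stays a leaf
    }
    if (F.origAttach == -999) F.origAttach = 0;
    for (int i = 0; i < F.tr.nedge(); ++i) F.attach.push_back(i);
    if (F.tr.nedge() == 0) {
      F.attach.clear();
      F.attach.push_back(-1 - cut);
      F.origAttach = -1 - cut;
    }
  };
  build(a0, true, A);
  build(b0, false, B);
}

// Join two fragments at the given attachment points.  newNode1/newNode2
// are fresh internal ids for subdividing chosen edges.
Tree joinFragments(const Fragment& A, int pa, const Fragment& B, int pb,
                   int newNode1, int newNode2) {
  Tree out;
  int endA, endB;
  out = A.tr;
  if (pa < 0) {
    endA = -1 - pa;
  } else {
    int u = out.a[pa], v = out.b[pa];
    out.a[pa] = u;
    out.b[pa] = newNode1;
    out.add(newNode1, v);
    endA = newNode1;
  }
  int off = out.nedge();
  (void)off;
  for (int i = 0; i < B.tr.nedge(); ++i) out.add(B.tr.a[i], B.tr.b[i]);
  if (pb < 0) {
    endB = -1 - pb;
  } else {
    int idx = out.nedge() - B.tr.nedge() + pb;
    int u = out.a[idx], v = out.b[idx];
    out.a[idx] = u;
    out.b[idx] = newNode2;
    out.add(newNode2, v);
    endB = newNode2;
  }
  out.add(endA, endB);
  return out;
}

// Enumerate branch-swap neighbours (raw node ids, not normalised;
// ids stay below 2*nTip so the scoring buffers fit).
// swap: 0 = NNI, 1 = SPR, 2 = TBR.
std::vector<Tree> neighbours(const Tree& tr, int nTip, int swap) {
  std::vector<Tree> out;
  int fresh1 = 2 * nTip - 2, fresh2 = 2 * nTip - 1;  // transient ids
  if (swap == 0) {
    // NNI on internal edges: exchange one subtree across the edge
    for (int i = 0; i < tr.nedge(); ++i) {
      int a0 = tr.a[i], b0 = tr.b[i];
      if (a0 < nTip || b0 < nTip) continue;
      std::vector<int> ea, eb;
      for (int j = 0; j < tr.nedge(); ++j) {
        if (j == i) continue;
        if (tr.a[j] == a0 || tr.b[j] == a0) ea.push_back(j);
        if (tr.a[j] == b0 || tr.b[j] == b0) eb.push_back(j);
      }
      // swap the subtree hanging on ea[1] with each of b0's subtrees
      for (int k = 0; k < 2; ++k) {
        Tree t2 = tr;
        int je = ea[1], jb = eb[k];
        if (t2.a[je] == a0) t2.a[je] = b0; else t2.b[je] = b0;
        if (t2.a[jb] == b0) t2.a[jb] = a0; else t2.b[jb] = a0;
        out.push_back(t2);
      }
    }
    return out;
  }
  for (int i = 0; i < tr.nedge(); ++i) {
    Fragment A, B;
    bisect(tr, i, nTip, A, B);
    if (swap == 2) {
      for (int pa : A.attach)
        for (int pb : B.attach) {
          if (pa == A.origAttach && pb == B.origAttach) continue;
          out.push_back(joinFragments(A, pa, B, pb, fresh1, fresh2));
        }
    } else {
      // SPR: regraft one side at its original point, vary the other
      for (int pa : A.attach) {
        if (pa == A.origAttach) continue;
        out.push_back(joinFragments(A, pa, B, B.origAttach, fresh1, fresh2));
      }
      for (int pb : B.attach) {
        if (pb == B.origAttach) continue;
        out.push_back(joinFragments(A, A.origAttach, B, pb, fresh1, fresh2));
      }
    }
  }
  return out;
}

Tree threeTaxonTree(int t0, int t1, int t2, int nTip) {
  Tree tr;
  tr.add(nTip, t0);
  tr.add(nTip, t1);
  tr.add(nTip, t2);
  return tr;
}

// Greedy stepwise addition following `order`; first-found ties.
Tree stepwiseAddition(Engine& eng, const std::vector<int>& order) {
  int n = eng.nTip;
  Tree tr = threeTaxonTree(order[0], order[1], order[2], n);
  int nextInternal = n + 1;
  for (size_t k = 3; k < order.size(); ++k) {
    int t = order[k];
    int bestEdge = -1, bestLen = INT_MAX;
    for (int ei = 0; ei < tr.nedge(); ++ei) {
      Tree cand = insertTip(tr, ei, t, nextInternal);
      int len = eng.fitch(cand, order[0], bestLen);
      if (len < bestLen) {
        bestLen = len;
        bestEdge = ei;
      }
    }
    tr = insertTip(tr, bestEdge, t, nextInternal);
    ++nextInternal;
  }
  return normalize(tr, n);
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_fitch_lengths(IntegerMatrix edge, int nTip,
                                IntegerMatrix tipStates) {
  Engine eng(nTip, tipStates.ncol(), tipStates);
  Tree tr = fromEdgeMatrix(edge, nTip);
  std::vector<int> perChar;
  eng.fitch(tr, 0, -1, &perChar);
  return wrap(perChar);
}

// Heuristic search: random-addition replicates (orders supplied from R,
// 1-based) + branch swapping.  All replicates share one island store:
// a replicate strictly better than the global best resets it; a
// replicate tying the global best joins the plateau walk, which
// collects and swaps through every equal-best topology not yet seen
// (up to maxTrees).  Replicates stuck above the global best stop after
// hill climbing, without exploring their own plateau.
// [[Rcpp::export]]
List cpp_heuristic_search(IntegerMatrix tipStates, IntegerMatrix orders,
                          int swap, int maxTrees) {
  int nTip = tipStates.nrow();
  Engine eng(nTip, tipStates.ncol(), tipStates);
  int globalBest = INT_MAX;
  std::set<std::vector<uint64_t>> globalSeen;
  std::vector<Tree> globalTrees;
  bool overflow = false;
  long swapCount = 0;
  IntegerVector repLen(orders.nrow());
  std::deque<Tree> queue;

  auto offerGlobal = [&](const Tree& t, bool enqueue) {
    auto sig = eng.signature(t);
    if (globalSeen.find(sig) != globalSeen.end()) return;
    if ((int)globalTrees.size() >= maxTrees) {
      overflow = true;
      return;
    }
    globalSeen.insert(sig);
    globalTrees.push_back(normalize(t, nTip));
    if (enqueue) queue.push_back(globalTrees.back());
  };

  for (int r = 0; r < orders.nrow(); ++r) {
    std::vector<int> order(nTip);
    for (int k = 0; k < nTip; ++k) order[k] = orders(r, k) - 1;
    Tree cur = stepwiseAddition(eng, order);
    int curLen = eng.fitch(cur, 0);
    // hill-climbing phase: strict improvements only
    for (;;) {
      if (curLen <= globalBest) break;
      std::vector<Tree> nb = neighbours(cur, nTip, swap);
      swapCount += (long)nb.size();
      int bestLen = curLen;
      int bestIdx = -1;
      for (size_t i = 0; i < nb.size(); ++i) {
        int len = eng.fitch(nb[i], 0, bestLen - 1);
        if (len < bestLen) {
          bestLen = len;
          bestIdx = (int)i;
        }
      }
      if (bestIdx < 0) break;  // local optimum above the global best
      cur = normalize(nb[bestIdx], nTip);
      curLen = bestLen;
      Rcpp::checkUserInterrupt();
    }
    if (curLen < globalBest) {
      globalBest = curLen;
      globalSeen.clear();
      globalTrees.clear();
      queue.clear();
    }
    if (curLen == globalBest) {
      offerGlobal(cur, true);
      // plateau walk: swap through every held tree, catching both
      // further improvements and new equal-best topologies
      while (!queue.empty()) {
        Tree t = queue.front();
        queue.pop_front();
        std::vector<Tree> nb = neighbours(t, nTip, swap);
        swapCount += (long)nb.size();
        for (Tree& cand : nb) {
          int len = eng.fitch(cand, 0, globalBest);
          if (len < globalBest) {
            globalBest = len;
            globalSeen.clear();
            globalTrees.clear();
            queue.clear();
            offerGlobal(cand, true);
            break;
          } else if (len == globalBest) {
            offerGlobal(cand, true);
          }
        }
        Rcpp::checkUserInterrupt();
      }
    }
    repLen[r] = curLen;
  }
  CharacterVector newicks(globalTrees.size());
  for (size_t i = 0; i < globalTrees.size(); ++i)
    newicks[i] = toNewick(globalTrees[i], nTip);
  return List::create(_["best_length"] = globalBest, _["trees"] = newicks,
                      _["replicate_length"] = repLen,
                      _["rearrangements"] = (double)swapCount,
                      _["overflow"] = overflow);
}

// Exact branch-and-bound over all unrooted binary topologies, taxa added
// in input order.  Returns all minimum-length trees.
// [[Rcpp::export]]
List cpp_branch_and_bound(IntegerMatrix tipStates) {
  int nTip = tipStates.nrow();
  int nChar = tipStates.ncol();
  Engine eng(nTip, nChar, tipStates);

  // remaining lower bound: states observed as single-state cells among
  // taxa >= k that no earlier taxon can carry
  std::vector<std::vector<uint32_t>> singAfter(nTip + 1,
                                               std::vector<uint32_t>(nChar, 0));
  for (int k = nTip - 1; k >= 0; --k) {
    singAfter[k] = singAfter[k + 1];
    for (int c = 0; c < nChar; ++c) {
      uint32_t m = eng.tip[(size_t)k * nChar + c];
      if (m && !(m & (m - 1))) singAfter[k][c] |= m;  // single state
    }
  }
  std::vector<std::vector<uint32_t>> unionBefore(nTip + 1,
                                                 std::vector<uint32_t>(nChar, 0));
  for (int k = 1; k <= nTip; ++k) {
    unionBefore[k] = unionBefore[k - 1];
    for (int c = 0; c < nChar; ++c)
      unionBefore[k][c] |= eng.tip[(size_t)(k - 1) * nChar + c];
  }
  auto lowerExtra = [&](int k) {
    int extra = 0;
    for (int c = 0; c < nChar; ++c) {
      uint32_t need = singAfter[k][c] & ~unionBefore[k][c];
      while (need) { need &= need - 1; ++extra; }
    }
    return extra;
  };

  // incumbent from greedy addition in input order
  std::vector<int> order(nTip);
  for (int i = 0; i < nTip; ++i) order[i] = i;
  Tree greedy = stepwiseAddition(eng, order);
  int incumbent = eng.fitch(greedy, 0);

  std::vector<Tree> bestTrees;
  std::function<void(Tree&, int, int)> rec = [&](Tree& tr, int k, int nextInternal) {
    if (k == nTip) {
      int len = eng.fitch(tr, 0);
      if (len < incumbent) {
        incumbent = len;
        bestTrees.clear();
      }
      if (len == incumbent) bestTrees.push_back(normalize(tr, nTip));
      return;
    }
    Rcpp::checkUserInterrupt();
    // states still required by taxa not in the candidate (> k), each
    // costing at least one change beyond the candidate's length
    int extra = lowerExtra(k + 1);
    for (int ei = 0, ne = tr.nedge(); ei < ne; ++ei) {
      Tree cand = insertTip(tr, ei, k, nextInternal);
      int len = eng.fitch(cand, 0, incumbent);
      if (len + extra <= incumbent) rec(cand, k + 1, nextInternal + 1);
    }
  };
  if (nTip == 3) {
    Tree tr = threeTaxonTree(0, 1, 2, nTip);
    bestTrees.push_back(tr);
    incumbent = eng.fitch(tr, 0);
  } else {
    Tree tr = threeTaxonTree(0, 1, 2, nTip);
    rec(tr, 3, nTip + 1);
    // a strictly better tree may have been found late; re-filter
    std::vector<Tree> keep;
    for (Tree& t : bestTrees)
      if (eng.fitch(t, 0) == incumbent) keep.push_back(t);
    bestTrees.swap(keep);
  }
  CharacterVector newicks(bestTrees.size());
  for (size_t i = 0; i < bestTrees.size(); ++i)
    newicks[i] = toNewick(bestTrees[i], nTip);
  return List::create(_["best_length"] = incumbent, _["trees"] = newicks);
}

// Bipartition signatures of a set of trees given as ape edge matrices,
// used for fast topology identity from R.
// [[Rcpp::export]]
CharacterVector cpp_signature(IntegerMatrix edge, int nTip) {
  Engine eng(nTip, 1, IntegerMatrix(nTip, 1));
  Tree tr = fromEdgeMatrix(edge, nTip);
  auto sig = eng.signature(tr);
  CharacterVector out(sig.size());
  for (size_t i = 0; i < sig.size(); ++i) {
    char buf[32];
    snprintf(buf, sizeof(buf), "%llx", (unsigned long long)sig[i]);
    out[i] = buf;
  }
  return out;
}
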