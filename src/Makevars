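# The convolution kernels dominate training time; compile them with full
# optimisation for the build host (the site flags pin -O2 and a generic
# -march).  The explicit rule takes precedence over the default suffix rule,
# and flags appended after $(ALL_CXXFLAGS) win the command-line duel.
HOTFLAGS = -O3 -funroll-loops -march=native

all: $(SHLIB)

convops.o: convops.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(HOTFLAGS) -c convops.cpp -o convops.o
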