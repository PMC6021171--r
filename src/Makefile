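# Build with the system toolchain: the cross-compiler shipped alongside R
# in this stack targets a newer glibc sysroot than the runtime loader
# provides, so its objects fail to load. Plain g++ against the running
# glibc avoids that.

RCPP_INC = $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(system.file("include", package = "Rcpp"))')
CXXFLAGS_PKG = -std=gnu++17 -O2 -fPIC -I"$(R_HOME)/include" -I"$(RCPP_INC)"

OBJECTS = RcppExports.o burst_search.o simulate_confocal.o

all: plugdyn.so

plugdyn.so: $(OBJECTS)
	g++ -shared -o $@ $(OBJECTS) -L"$(R_HOME)/lib" -lR

%.o: %.cpp
	g++ $(CXXFLAGS_PKG) -c $< -o $@

clean:
	rm -f $(OBJECTS) plugdyn.so

.PHONY: all clean
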