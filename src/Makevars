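# Build with the system toolchain: the conda cross-compiler emits references
# to glibc 2.38 symbols that the runtime loader (glibc 2.35) cannot resolve.
override CC = /usr/bin/gcc
override CXX = /usr/bin/g++
override CXX17 = /usr/bin/g++ -std=gnu++17
override CXXFLAGS = -O2 -fPIC
override CXX17FLAGS = -O2 -fPIC
override CFLAGS = -O2 -fPIC
override SHLIB_CXXLD = /usr/bin/g++ -std=gnu++17
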