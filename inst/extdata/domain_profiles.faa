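>RT_core
EHMYFVDPYPDGKTQFRCRQGFKLSSFEPFVANGTQQYLQLPFELEALPLQPGIKITLDLKDAYFQIPLFVNEKEMHVWPRRPWKSETHDECSIWQLNTVWMNDREHGLTFHSCELWRVGYVDDILVFDNIHYSRRGLGQWMYIAEMGENDEFLNWKKCENCYPAAWMQKMYACCAESLE
>RNaseH
SVDCIMEIMAVTPVFTPVFTDGSARGLEDTICWYMFQIGIPNDSIGIHQGFRDYCLMWWIAGNIGMWFCDAEHLDTQPSITDSQKFDEPPMGYEWMDAKICFREPHCKVAPVQRFDVGIR
>AP
KLCIMNNYASRNPDKGLESCIKRKHRNLLDTGADVTTCKTNWIRPDMLIRPARGWSPDENGCQLQSIIGVSIRITTWEIYIVNWFVAKLM
>MP
PDWFCKKWEPFLGLVGTQTEKDISLWRPEVKMMPKNQGNGDLNPLSGGQWDHQWPQAPPICWYKMDYMPTAMFQFWPHVVLYCRELCVCRMAIFPKWNEALHMRSKADAALHMFFGTMDKYCYYTIAPKFSKWYICNNTE
>zf_CCHC
YALFYLMCYNCGKPGHIARDCRGFIEFCFKCGQMGHFMDHEMHQG
>integrase
YYTGVNISTHLHCQYAPATYCSCTVSWICCVISHHHFFNEVLSQPPCRMGIDLMGPFGIDAKNTTTNLFGDQLFAYIYESDNGPAFISQTTYEGDPREYTIHAHWHTNPYIEMHIWFSLQWAEHLAKNPGYMQWGMRDRD
>transposase
HFRCWTWVKVCCGLVYNELLNNQWWIDETGGTACIYIFHVSYYIDAMWQHFWRLDMLYSWLGENQSIEKGDVKVMCCKEVRFGLRLDADEREPTCGWEWKGRCVWAMTSVMKRYTACQLRRLIGMNKWGC
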