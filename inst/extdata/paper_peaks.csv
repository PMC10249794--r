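sample,assay,base,intensity
SFP_pre,067721-477,G,5.3
SFP_pre,067721-477,A,1.6
SFP_pre,067721-477,C,1.2
SFP_pre,067721-477,T,1.6
SFP_post,067721-477,G,8.4
SFP_post,067721-477,A,2.8
SFP_post,067721-477,C,0.4
SFP_post,067721-477,T,0.9
SFP_failure,067721-477,G,7.0
SFP_failure,067721-477,A,1.8
SFP_failure,067721-477,C,―
SFP_failure,067721-477,T,0.7
SFP_pre,067744-324,C,41
SFP_pre,067744-324,T,58
SFP_pre,067744-324,G,―
SFP_pre,067744-324,A,9.0
SFP_post,067744-324,C,53
SFP_post,067744-324,T,5.0
SFP_post,067744-324,G,1.0
SFP_post,067744-324,A,7.0
SFP_failure,067744-324,C,68
SFP_failure,067744-324,T,4.5
SFP_failure,067744-324,G,―
SFP_failure,067744-324,A,8.0
ascospore_full,067721-477,G,7.5
ascospore_full,067721-477,A,3.0
ascospore_full,067721-477,C,―
ascospore_full,067721-477,T,0.5
ascospore_semi,067721-477,G,6.9
ascospore_semi,067721-477,A,3.2
ascospore_semi,067721-477,C,―
ascospore_semi,067721-477,T,0.5
ascospore_full,067740-324,C,15.4
ascospore_full,067740-324,T,22.3
ascospore_full,067740-324,A,1.7
ascospore_full,067740-324,G,1.0
ascospore_semi,067740-324,C,34.8
ascospore_semi,067740-324,T,26.8
ascospore_semi,067740-324,A,2.4
ascospore_semi,067740-324,G,1.9
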